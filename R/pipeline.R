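#' End-to-end evaluation pipeline configuration
#'
#' Describes one of the two evaluation designs: the expert path (a fixed
#' sliding-window rule, optionally preceded by a grid search over its
#' parameters) or the LSTM path (patient-level k-fold cross-validation of
#' the learned slice labeler).
#'
#' @param detector `"expert"` or `"lstm"`.
#' @param rule A [rule_config()] for the fixed expert rule.
#' @param grid Optional [grid_spec()]; when given, the expert rule is
#'   grid-searched on the provided cohort before evaluation (an in-sample
#'   choice, flagged as such in the report).
#' @param detector_spec A [detector_spec()] for the LSTM path.
#' @param training A [training_config()] for the LSTM path.
#' @param k_folds Folds for the LSTM path (default 5, must be >= 2).
#' @param seed Pipeline seed; overrides the training config's seed so one
#'   value controls fold assignment, weight init and batch order.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detector = c("expert", "lstm"),
                            rule = rule_config(), grid = NULL,
                            detector_spec = aaaquant::detector_spec(),
                            training = training_config(), k_folds = 5L,
                            seed = 1L) {
  detector <- match.arg(detector)
  stopifnot(inherits(rule, "rule_config"),
            is.null(grid) || inherits(grid, "grid_spec"),
            inherits(detector_spec, "detector_spec"),
            inherits(training, "training_config"))
  if (detector == "lstm" && k_folds < 2L) {
    stop("the lstm path needs k_folds >= 2", call. = FALSE)
  }
  structure(
    list(detector = detector, rule = rule, grid = grid,
         detector_spec = detector_spec, training = training,
         k_folds = as.integer(k_folds), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run a full boundary-detection evaluation on a cohort
#'
#' Expert path: optionally grid-search the rule on the cohort (in-sample,
#' reported as such), detect boundaries per patient, and evaluate against
#' the annotations. LSTM path: patient-level k-fold cross-validation
#' followed by pooling of the fold reports. Deterministic given the config
#' seed.
#'
#' @param cohort An annotated [cohort()].
#' @param cfg A [pipeline_config()].
#' @param verbose Print one line per patient decision on the expert path
#'   and training progress on the LSTM path.
#' @return List of class `pipeline_result`: `report` (an [eval_report()]),
#'   `predictions` (expert path), `rule` (the rule used, grid-searched or
#'   fixed), `grid_objective`, `folds` and `cv` (LSTM path), and `config`.
#' @export
run_evaluation <- function(cohort, cfg = pipeline_config(),
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "aaa_cohort"),
            inherits(cfg, "pipeline_config"))
  if (length(cohort$annotations) == 0L) {
    stop("run_evaluation needs an annotated cohort", call. = FALSE)
  }
  if (cfg$detector == "expert") {
    rule <- cfg$rule
    grid_objective <- NULL
    if (!is.null(cfg$grid)) {
      gs <- grid_search(cohort, cfg$grid)
      rule <- gs$config
      grid_objective <- gs$objective
      if (verbose) {
        message(sprintf(
          "grid search (in-sample): window %d, upper %.2f, lower %.2f, mean Dice %.3f",
          rule$window, rule$upper, rule$lower, gs$objective))
      }
    }
    predictions <- lapply(names(cohort$annotations), function(id) {
      pred <- detect_boundaries_expert(cohort$profiles[[id]], rule)
      if (verbose) {
        message(sprintf("%s: %s", id,
                        if (pred$present)
                          sprintf("region [%d, %d]", pred$start, pred$end)
                        else "no region"))
      }
      pred
    })
    tag <- if (is.null(cfg$grid)) "expert (fixed rule)"
           else "expert (grid-searched in-sample)"
    report <- evaluate_cohort(cohort, predictions, detector = tag)
    structure(list(report = report, predictions = predictions, rule = rule,
                   grid_objective = grid_objective, config = cfg),
              class = "pipeline_result")
  } else {
    training <- cfg$training
    training$seed <- cfg$seed
    cv <- cross_validate(cohort, k = cfg$k_folds, spec = cfg$detector_spec,
                         cfg = training, verbose = verbose)
    structure(list(report = cv$pooled, folds = cv$folds, cv = cv,
                   config = cfg),
              class = "pipeline_result")
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> detector: %s\n", x$config$detector))
  print(x$report)
  invisible(x)
}
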