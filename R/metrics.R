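#' Dice coefficient between two slice-index intervals
#'
#' Treats each annotation as the set of slices it covers and computes
#' `2*TP / (2*TP + FP + FN)` on those sets. Two absent annotations agree
#' perfectly (Dice 1); an absent prediction against a present truth (or the
#' reverse) scores 0.
#'
#' @param pred,truth [boundary_annotation()] objects for the same profile.
#' @return Dice overlap in `[0, 1]`.
#' @examples
#' interval_dice(boundary_annotation("p", 0, 9),
#'               boundary_annotation("p", 5, 14))  # 0.5
#' @export
interval_dice <- function(pred, truth) {
  stopifnot(inherits(pred, "boundary_annotation"),
            inherits(truth, "boundary_annotation"))
  if (!pred$present && !truth$present) return(1)
  if (!pred$present || !truth$present) return(0)
  inter <- max(0L, min(pred$end, truth$end) - max(pred$start, truth$start) + 1L)
  len_p <- pred$end - pred$start + 1L
  len_t <- truth$end - truth$start + 1L
  2 * inter / (len_p + len_t)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS` with `RSS = sum((truth - pred)^2)` and
#' `TSS = sum((truth - mean(truth))^2)`. This is the direct formula applied
#' to paired values (e.g. predicted vs annotated start slices), not the R^2
#' of a fitted regression; it can be negative when predictions do worse than
#' the truth mean.
#'
#' @param truth,pred Equal-length numeric vectors (length >= 2); `truth`
#'   must not be constant.
#' @return R-squared, at most 1.
#' @export
r_squared <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2)
  tss <- sum((truth - mean(truth))^2)
  if (tss == 0) {
    stop("R^2 undefined for constant ground truth (TSS = 0)", call. = FALSE)
  }
  1 - sum((truth - pred)^2) / tss
}

#' Mean absolute and mean squared error
#'
#' @param truth,pred Equal-length non-empty numeric vectors.
#' @return Named list with `mae` and `mse`.
#' @export
mae_mse <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0L) stop("empty vectors", call. = FALSE)
  list(mae = mean(abs(truth - pred)), mse = mean((truth - pred)^2))
}

#' Binary cross-entropy
#'
#' Negative mean log-likelihood of binary targets under predicted
#' probabilities, with probabilities clipped to `[clip_eps, 1 - clip_eps]`
#' for numerical stability. This is the slice-labeling training loss
#' monitored during LSTM optimization.
#'
#' @param truth Binary vector (0/1).
#' @param probs Probability vector in `[0, 1]`, same length.
#' @param clip_eps Clipping bound, default `1e-7`.
#' @return Non-negative scalar loss.
#' @export
bce <- function(truth, probs, clip_eps = 1e-7) {
  if (length(truth) != length(probs)) {
    stop("truth and probs must have equal length", call. = FALSE)
  }
  stopifnot(all(truth %in% c(0, 1)), all(probs >= 0), all(probs <= 1),
            clip_eps > 0, clip_eps < 0.5)
  p <- pmin(pmax(probs, clip_eps), 1 - clip_eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Surrogate aneurysm volume
#'
#' Sum of segmented-pixel counts over the annotated slice interval,
#' inclusive of both boundaries. The result is a unit-less volume surrogate:
#' it scales linearly with true physical volume but carries no slice
#' thickness or pixel-size calibration.
#'
#' @param profile A [slice_profile()].
#' @param ann A present [boundary_annotation()] within the profile.
#' @return Non-negative integer pixel sum.
#' @export
volume_surrogate <- function(profile, ann) {
  stopifnot(inherits(profile, "slice_profile"),
            inherits(ann, "boundary_annotation"))
  if (!ann$present) {
    stop("surrogate volume undefined for an absent annotation", call. = FALSE)
  }
  if (ann$end >= profile$slice_count) {
    stop("annotation extends beyond profile", call. = FALSE)
  }
  sum(profile$counts[(ann$start + 1L):(ann$end + 1L)])
}

#' Enlargement above an interpolated normal baseline
#'
#' Estimates how much the aneurysm exceeds normal aortic caliber: a straight
#' line between the counts at the start and end boundary slices stands in
#' for the normal vessel, and the positive excess of the observed counts
#' over that baseline is summed. Dips below the baseline contribute zero, so
#' the statistic is non-negative by construction. A zero-length interval
#' (`start == end`) has no interior and returns 0.
#'
#' @inheritParams volume_surrogate
#' @return Non-negative enlargement surrogate (pixels).
#' @export
enlargement_surrogate <- function(profile, ann) {
  stopifnot(inherits(profile, "slice_profile"),
            inherits(ann, "boundary_annotation"))
  if (!ann$present) {
    stop("enlargement undefined for an absent annotation", call. = FALSE)
  }
  if (ann$end >= profile$slice_count) {
    stop("annotation extends beyond profile", call. = FALSE)
  }
  if (ann$start == ann$end) return(0)
  idx <- ann$start:ann$end
  y <- profile$counts[idx + 1L]
  baseline <- y[1] + (y[length(y)] - y[1]) * (idx - ann$start) /
    (ann$end - ann$start)
  sum(pmax(0, y - baseline))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall, specificity and F1 for a binary
#' aneurysm-vs-normal screen (aneurysm is the positive class), reported as
#' percentages rounded to one decimal. A metric whose denominator is zero is
#' returned as `NULL`.
#'
#' @param tp,fp,fn,tn Non-negative confusion-matrix cell counts.
#' @return Named list of percentages (or `NULL` entries).
#' @examples
#' classification_metrics(tp = 15, fp = 2, fn = 2, tn = 14)
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), sum(cells) >= 1)
  pct <- function(num, den) if (den == 0) NULL else round(100 * num / den, 1)
  list(
    accuracy    = pct(tp + tn, tp + fp + fn + tn),
    precision   = pct(tp, tp + fp),
    recall      = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    f1          = pct(2 * tp, 2 * tp + fp + fn)
  )
}

#' Construct an evaluation report
#'
#' The cohort-level result schema: mean interval Dice, boundary R-squared /
#' MAE / MSE for start and end slices, surrogate-volume R-squared, and the
#' counts of predicted and missed aneurysms. Metrics that are undefined
#' (no usable predictions) are `NULL`.
#'
#' @param mean_dice Mean interval Dice over the cohort.
#' @param r2_start,r2_end,r2_volume R-squared values or `NULL`.
#' @param mae_start,mae_end,mse_start,mse_end Error values or `NULL`.
#' @param n_predicted,n_missed Patient counts; they sum to the cohort size.
#' @param detector Optional character tag for the detector that produced the
#'   predictions.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(mean_dice, r2_start = NULL, r2_end = NULL,
                        r2_volume = NULL, mae_start = NULL, mae_end = NULL,
                        mse_start = NULL, mse_end = NULL,
                        n_predicted = 0L, n_missed = 0L, detector = NULL) {
  structure(
    list(mean_dice = mean_dice, r2_start = r2_start, r2_end = r2_end,
         r2_volume = r2_volume, mae_start = mae_start, mae_end = mae_end,
         mse_start = mse_start, mse_end = mse_end,
         n_predicted = as.integer(n_predicted),
         n_missed = as.integer(n_missed), detector = detector),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf(
    paste0("<eval_report>%s\n",
           "  mean Dice %s | R2 start %s end %s volume %s\n",
           "  MAE start %s end %s | MSE start %s end %s\n",
           "  predicted %d, missed %d\n"),
    if (is.null(x$detector)) "" else paste0(" [", x$detector, "]"),
    fmt(x$mean_dice), fmt(x$r2_start), fmt(x$r2_end), fmt(x$r2_volume),
    fmt(x$mae_start), fmt(x$mae_end), fmt(x$mse_start), fmt(x$mse_end),
    x$n_predicted, x$n_missed))
  invisible(x)
}

#' Evaluate predicted boundaries against a cohort's annotations
#'
#' Mean interval Dice is averaged over every annotated patient; a patient
#' with no prediction contributes Dice 0. Boundary regressions (R-squared,
#' MAE, MSE on start and end slice indices) and the surrogate-volume
#' R-squared use only patients where both the annotation and the prediction
#' mark an aneurysm, so a missed detection lowers the Dice average and the
#' `n_missed` count but does not poison the regressions. `n_missed` counts
#' annotated aneurysms with no (or an absent) prediction; `n_predicted` is
#' the remainder of the cohort.
#'
#' @param cohort An annotated [cohort()].
#' @param predictions List of [boundary_annotation()] predictions, keyed or
#'   identified by `patient_id`; every id must exist in the cohort.
#' @param detector Optional character tag recorded in the report.
#' @return An [eval_report()].
#' @export
evaluate_cohort <- function(cohort, predictions, detector = NULL) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  if (length(cohort$annotations) == 0L) {
    stop("cohort has no annotations to evaluate against", call. = FALSE)
  }
  pred_ids <- vapply(predictions, function(p) p$patient_id, character(1))
  unknown <- setdiff(pred_ids, names(cohort$profiles))
  if (length(unknown)) {
    stop("predictions for unknown patients: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  names(predictions) <- pred_ids

  ids <- names(cohort$annotations)
  dice <- numeric(length(ids))
  ts <- te <- ps <- pe <- tv <- pv <- numeric(0)
  n_missed <- 0L
  for (k in seq_along(ids)) {
    id <- ids[k]
    truth <- cohort$annotations[[id]]
    pred <- predictions[[id]] %||% boundary_annotation(id, present = FALSE)
    dice[k] <- interval_dice(pred, truth)
    if (truth$present && !pred$present) n_missed <- n_missed + 1L
    if (truth$present && pred$present) {
      profile <- cohort$profiles[[id]]
      ts <- c(ts, truth$start); te <- c(te, truth$end)
      ps <- c(ps, pred$start);  pe <- c(pe, pred$end)
      tv <- c(tv, volume_surrogate(profile, truth))
      pv <- c(pv, volume_surrogate(profile, pred))
    }
  }
  safe_r2 <- function(t, p) {
    if (length(t) < 2 || stats::var(t) == 0) NULL else r_squared(t, p)
  }
  if (length(ts)) {
    es <- mae_mse(ts, ps)
    ee <- mae_mse(te, pe)
    report <- eval_report(
      mean_dice = mean(dice),
      r2_start = safe_r2(ts, ps), r2_end = safe_r2(te, pe),
      r2_volume = safe_r2(tv, pv),
      mae_start = es$mae, mae_end = ee$mae,
      mse_start = es$mse, mse_end = ee$mse,
      n_predicted = length(ids) - n_missed, n_missed = n_missed,
      detector = detector
    )
  } else {
    report <- eval_report(mean_dice = mean(dice),
                          n_predicted = length(ids) - n_missed,
                          n_missed = n_missed, detector = detector)
  }
  report
}
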