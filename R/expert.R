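#' Sliding-window rule configuration
#'
#' Parameters shared by the two rule-based systems: the number of preceding
#' slices averaged into the rolling baseline (`window`), the relative
#' thresholds flagging a slice as anomalously large (`upper`) or small
#' (`lower`) with respect to that baseline, and, for the screen, how many
#' consecutive anomalous slices are required before a profile is called
#' aneurysmal (`persistence`).
#'
#' Defaults follow the boundary detector's printed thresholds: a slice
#' exceeding 120 percent of the rolling average marks a start and one
#' dropping below 80 percent marks an end, with a window of four slices.
#' The dropout screen uses [screen_defaults()] (140 / 50 percent) instead.
#'
#' @param window Integer >= 1, slices in the rolling baseline.
#' @param upper Ratio > 1 for the enlargement threshold.
#' @param lower Ratio in (0, 1) for the drop threshold.
#' @param persistence Integer >= 1, consecutive anomalous slices required by
#'   the screen.
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(window = 4L, upper = 1.2, lower = 0.8,
                        persistence = 4L) {
  window <- as.integer(window)
  persistence <- as.integer(persistence)
  stopifnot(window >= 1L, persistence >= 1L,
            upper > 1, lower > 0, lower < 1)
  structure(list(window = window, upper = upper, lower = lower,
                 persistence = persistence),
            class = "rule_config")
}

#' Default configuration for the segmentation-failure screen
#'
#' Rolling average over four slices, anomaly when a count drops below 50
#' percent or exceeds 140 percent of the baseline, and four consecutive
#' anomalous slices required to call the scan aneurysmal.
#'
#' @return A [rule_config()].
#' @export
screen_defaults <- function() rule_config(window = 4L, upper = 1.4,
                                          lower = 0.5, persistence = 4L)

# Per-slice anomaly flags against a rolling normal baseline.
#
# The baseline at each slice is the mean of the `window` most recent slices
# judged normal so far: the first `window` slices seed it (and are never
# flagged), and a flagged slice is excluded, so the baseline tracks normal
# aortic caliber through an anomaly instead of being dragged along by it.
# A slice is up-flagged when its count exceeds `upper` times the baseline
# and down-flagged when it falls below `lower` times the baseline.
anomaly_flags <- function(counts, config) {
  n <- length(counts)
  w <- config$window
  up <- logical(n)
  down <- logical(n)
  base <- rep(NA_real_, n)
  recent <- as.numeric(counts[seq_len(min(w, n))])
  if (n > w) {
    for (i in (w + 1L):n) {
      b <- mean(recent)
      base[i] <- b
      if (counts[i] > config$upper * b) {
        up[i] <- TRUE
      } else if (counts[i] < config$lower * b) {
        down[i] <- TRUE
      } else {
        recent <- c(recent[-1L], counts[i])
      }
    }
  }
  list(up = up, down = down, base = base)
}

# maximal runs of TRUE in a logical vector, as a data.frame of 1-based
# start/end positions
true_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Screen a profile for segmentation failure
#'
#' A binary aneurysm-vs-normal classifier exploiting the tendency of a
#' segmentation model trained only on normal anatomy to stop producing
#' masks (or produce wildly different areas) on pathological slices. A
#' rolling average of the `window` most recent normal slices is the local
#' normal baseline; a slice is anomalous when its count falls below
#' `lower` times or rises above `upper` times that baseline. If any run of
#' at least `persistence` consecutive anomalous slices exists, the profile
#' is labeled aneurysmal, the first slice of any qualifying run is the
#' flagged start, and the last slice of any qualifying run the flagged end.
#'
#' @param profile A [slice_profile()] with more than
#'   `window + persistence - 1` slices.
#' @param config A [rule_config()]; defaults to [screen_defaults()].
#' @return A list of class `screen_result`: `patient_id`, `label`
#'   (`"aneurysm"` or `"normal"`), and 0-based `first_flagged` /
#'   `last_flagged` (NA when normal).
#' @export
screen_failure <- function(profile, config = screen_defaults()) {
  stopifnot(inherits(profile, "slice_profile"),
            inherits(config, "rule_config"))
  if (profile$slice_count < config$window + config$persistence) {
    stop(sprintf("profile %s too short (%d slices) for window %d + persistence %d",
                 profile$patient_id, profile$slice_count, config$window,
                 config$persistence), call. = FALSE)
  }
  flags <- anomaly_flags(profile$counts, config)
  runs <- true_runs(flags$up | flags$down)
  runs <- runs[runs$length >= config$persistence, , drop = FALSE]
  if (nrow(runs) == 0L) {
    res <- list(patient_id = profile$patient_id, label = "normal",
                first_flagged = NA_integer_, last_flagged = NA_integer_)
  } else {
    res <- list(patient_id = profile$patient_id, label = "aneurysm",
                first_flagged = min(runs$start) - 1L,   # back to 0-based
                last_flagged = max(runs$end) - 1L)
  }
  structure(res, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  if (x$label == "aneurysm") {
    cat(sprintf("<screen_result> %s: aneurysm, flagged slices [%d, %d]\n",
                x$patient_id, x$first_flagged, x$last_flagged))
  } else {
    cat(sprintf("<screen_result> %s: normal\n", x$patient_id))
  }
  invisible(x)
}

#' Detect aneurysm boundaries with the sliding-window expert rule
#'
#' Scans the pixel-count profile for a sustained deviation from normal
#' aortic caliber. The reference level at each slice is the rolling average
#' of the `window` most recent slices judged normal so far, so it tracks the
#' vessel's normal caliber up to the aneurysm and holds there while counts
#' are abnormal. A slice is anomalous when its count exceeds `upper` times
#' that baseline (the enlargement that opens an aneurysm) or falls below
#' `lower` times it (the collapse seen with segmentation dropout). Maximal
#' runs of at least `window` consecutive anomalous slices are the candidate
#' abnormality regions; the region of greatest slice extent is returned
#' (ties broken toward the earliest), its first and last slices being the
#' aneurysm start and end. With no qualifying region the annotation is
#' absent.
#'
#' Because thresholds are ratios to a rolling average, the detector is
#' invariant to rescaling all counts by a positive constant, and no detected
#' region can extend into the first `window` slices (they seed the
#' baseline).
#'
#' @param profile A [slice_profile()].
#' @param config A [rule_config()]; defaults to window 4, upper 1.2,
#'   lower 0.8.
#' @return A [boundary_annotation()] (possibly absent).
#' @export
detect_boundaries_expert <- function(profile, config = rule_config()) {
  stopifnot(inherits(profile, "slice_profile"),
            inherits(config, "rule_config"))
  if (profile$slice_count < 2L * config$window) {
    stop(sprintf("profile %s too short (%d slices) for window %d",
                 profile$patient_id, profile$slice_count, config$window),
         call. = FALSE)
  }
  flags <- anomaly_flags(profile$counts, config)
  runs <- true_runs(flags$up | flags$down)
  runs <- runs[runs$length >= max(config$window, 2L), , drop = FALSE]
  if (nrow(runs) == 0L) {
    return(boundary_annotation(profile$patient_id, present = FALSE))
  }
  best <- runs[order(-runs$length, runs$start)[1], ]
  boundary_annotation(profile$patient_id, best$start - 1L, best$end - 1L)
}

#' Grid specification for rule parameter search
#'
#' @param windows Integer vector of candidate window sizes.
#' @param uppers Numeric vector of candidate upper thresholds (> 1).
#' @param lowers Numeric vector of candidate lower thresholds in (0, 1).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(windows = 2:8,
                      uppers = seq(1.05, 1.50, by = 0.05),
                      lowers = seq(0.50, 0.95, by = 0.05)) {
  stopifnot(length(windows) >= 1, length(uppers) >= 1, length(lowers) >= 1,
            all(windows >= 1), all(uppers > 1), all(lowers > 0),
            all(lowers < 1))
  structure(list(windows = as.integer(windows), uppers = uppers,
                 lowers = lowers),
            class = "grid_spec")
}

#' Exhaustive grid search over rule parameters
#'
#' Evaluates [detect_boundaries_expert()] with every combination of window,
#' upper and lower threshold on the cohort's annotated profiles and returns
#' the configuration maximizing mean interval Dice. Ties are broken toward
#' the smaller window, then the upper threshold closest to 1, then the lower
#' threshold closest to 1, so the least aggressive rule wins among equals.
#'
#' @param cohort An annotated [cohort()].
#' @param grid A [grid_spec()].
#' @return A list with `config` (the winning [rule_config()]), `objective`
#'   (its mean Dice), and `table` (a data.frame of every grid point and its
#'   objective).
#' @export
grid_search <- function(cohort, grid = grid_spec()) {
  stopifnot(inherits(cohort, "aaa_cohort"), inherits(grid, "grid_spec"))
  ids <- names(cohort$annotations)
  if (length(ids) == 0L) {
    stop("grid search needs at least one annotated profile", call. = FALSE)
  }
  combos <- expand.grid(window = grid$windows, upper = grid$uppers,
                        lower = grid$lowers, KEEP.OUT.ATTRS = FALSE)
  combos$objective <- NA_real_
  for (i in seq_len(nrow(combos))) {
    cfg <- rule_config(combos$window[i], combos$upper[i], combos$lower[i])
    dice <- vapply(ids, function(id) {
      pred <- detect_boundaries_expert(cohort$profiles[[id]], cfg)
      interval_dice(pred, cohort$annotations[[id]])
    }, numeric(1))
    combos$objective[i] <- mean(dice)
  }
  ord <- order(-combos$objective, combos$window,
               combos$upper - 1, 1 - combos$lower)
  best <- combos[ord[1], ]
  list(config = rule_config(best$window, best$upper, best$lower),
       objective = best$objective,
       table = combos)
}
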