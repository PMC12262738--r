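# Independent step-through oracles and small fixture builders. These
# deliberately re-derive the rule logic slice by slice with plain loops and
# growing vectors, independent of the package's vectorized internals.

# Per-slice anomaly flags: the baseline before slice i (0-based) is the mean
# of the `window` most recent slices judged normal so far; the first
# `window` slices seed the history and are never flagged.
oracle_flags <- function(counts, window, upper, lower) {
  n <- length(counts)
  normal_history <- counts[1:window]
  flagged <- rep(FALSE, n)
  direction <- rep(NA_character_, n)
  if (n > window) {
    for (i in (window + 1):n) {
      base <- mean(utils::tail(normal_history, window))
      if (counts[i] > upper * base) {
        flagged[i] <- TRUE
        direction[i] <- "up"
      } else if (counts[i] < lower * base) {
        flagged[i] <- TRUE
        direction[i] <- "down"
      } else {
        normal_history <- c(normal_history, counts[i])
      }
    }
  }
  list(flagged = flagged, direction = direction)
}

# maximal runs of TRUE, as 0-based [start, end, length] rows
oracle_runs <- function(flagged) {
  out <- NULL
  i <- 1
  n <- length(flagged)
  while (i <= n) {
    if (flagged[i]) {
      j <- i
      while (j < n && flagged[j + 1]) j <- j + 1
      out <- rbind(out, c(start = i - 1, end = j - 1, length = j - i + 1))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# screen: label aneurysm iff some run of >= persistence anomalous slices
oracle_screen <- function(counts, window, upper, lower, persistence) {
  fl <- oracle_flags(counts, window, upper, lower)
  runs <- oracle_runs(fl$flagged)
  runs <- runs[runs[, "length"] >= persistence, , drop = FALSE]
  if (is.null(runs) || nrow(runs) == 0) {
    list(label = "normal", first = NA, last = NA)
  } else {
    list(label = "aneurysm", first = min(runs[, "start"]),
         last = max(runs[, "end"]))
  }
}

# boundary detector: largest anomalous run of length >= window
oracle_detect <- function(counts, window, upper, lower) {
  fl <- oracle_flags(counts, window, upper, lower)
  runs <- oracle_runs(fl$flagged)
  runs <- runs[runs[, "length"] >= max(window, 2), , drop = FALSE]
  if (is.null(runs) || nrow(runs) == 0) return(NULL)
  best <- runs[order(-runs[, "length"], runs[, "start"]), , drop = FALSE][1, ]
  c(start = unname(best["start"]), end = unname(best["end"]))
}

# small random step/bump profiles exercising both rule directions
random_rule_profile <- function(id, seed) {
  set.seed(seed)
  base <- sample(50:400, 1)
  n <- sample(60:120, 1)
  counts <- rep(base, n)
  kind <- sample(c("none", "bump", "dropout", "both"), 1)
  if (kind %in% c("bump", "both")) {
    w <- sample(8:20, 1)
    s <- sample(10:(n - w - 5), 1)
    counts[s:(s + w)] <- round(base * runif(w + 1, 1.5, 3))
  }
  if (kind %in% c("dropout", "both")) {
    w <- sample(5:15, 1)
    s <- sample(10:(n - w - 5), 1)
    counts[s:(s + w)] <- sample(0:round(0.2 * base), w + 1, replace = TRUE)
  }
  counts <- pmax(0L, as.integer(counts + round(rnorm(n, 0, 0.01 * base))))
  slice_profile(id, counts)
}

# brute-force disk pixel enumeration on a square grid (1-based centers)
disk_pixel_count <- function(grid, radius) {
  ctr <- (grid + 1) / 2
  cnt <- 0L
  for (x in 1:grid) {
    for (y in 1:grid) {
      if ((x - ctr)^2 + (y - ctr)^2 <= radius^2) cnt <- cnt + 1L
    }
  }
  cnt
}

# tiny annotated cohort for pipeline/lstm tests (short profiles, narrow bumps)
tiny_cohort <- function(n, seed, n_slices = 80L, noise = 0.02,
                        amplitude_range = c(2, 4),
                        halfwidth_range = c(8L, 12L)) {
  generate_cohort(n, 1, synthetic_params(n_slices = n_slices,
                                         noise_sd_frac = noise),
                  seed = seed, amplitude_range = amplitude_range,
                  halfwidth_range = halfwidth_range)
}

# compact detector spec used throughout the simulation tests
tiny_spec <- function(output_len = 80L) {
  detector_spec(recurrent_layers = 2L, hidden_units = 6L,
                fc_hidden = c(8L), output_len = output_len)
}
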