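test_that("interval Dice handles overlap, disjointness and absence", {
  ann <- function(s, e) boundary_annotation("p", s, e)
  none <- boundary_annotation("p", present = FALSE)
  expect_equal(interval_dice(ann(12, 40), ann(12, 40)), 1)
  expect_equal(interval_dice(ann(0, 9), ann(20, 29)), 0)
  # TP = 5, FP = 5, FN = 5 -> 10/20
  expect_equal(interval_dice(ann(0, 9), ann(5, 14)), 0.5)
  expect_equal(interval_dice(none, none), 1)
  expect_equal(interval_dice(none, ann(3, 8)), 0)
  expect_equal(interval_dice(ann(3, 8), none), 0)
})

test_that("interval Dice is symmetric, bounded, and 1 only at equality", {
  set.seed(9)
  for (i in 1:50) {
    a <- sort(sample(0:60, 2))
    b <- sort(sample(0:60, 2))
    pa <- boundary_annotation("p", a[1], a[2])
    pb <- boundary_annotation("p", b[1], b[2])
    d <- interval_dice(pa, pb)
    expect_equal(d, interval_dice(pb, pa))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d == 1, a[1] == b[1] && a[2] == b[2])
  }
})

test_that("r_squared follows the 1 - RSS/TSS closed form", {
  y <- c(3, 7, 1, 9, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # RSS 1, TSS 2
  expect_error(r_squared(rep(2, 4), 1:4), "constant")
  # shift invariance
  p <- c(2, 8, 0, 10, 3)
  expect_equal(r_squared(y + 100, p + 100), r_squared(y, p))
})

test_that("mae_mse computes mean absolute and squared errors", {
  expect_equal(mae_mse(c(1, 2), c(1, 2)), list(mae = 0, mse = 0))
  expect_equal(mae_mse(c(10, 20), c(12, 26)), list(mae = 4, mse = 20))
  expect_equal(mae_mse(5, 8), list(mae = 3, mse = 9))
  expect_error(mae_mse(numeric(0), numeric(0)), "empty")
})

test_that("bce is the negative mean log-likelihood", {
  expect_equal(bce(1, 0.5), -log(0.5))
  expect_equal(bce(0, 0.5), bce(1, 0.5))
  expect_lt(bce(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_error(bce(c(1, 0), 0.5), "equal length")
})

test_that("surrogate volume sums counts inclusively and additively", {
  prof <- slice_profile("p", c(5, 5, 5))
  expect_equal(volume_surrogate(prof, boundary_annotation("p", 0, 2)), 15)
  expect_equal(volume_surrogate(prof, boundary_annotation("p", 1, 1)), 5)
  expect_error(
    volume_surrogate(prof, boundary_annotation("p", present = FALSE)),
    "absent")

  set.seed(3)
  rp <- slice_profile("r", sample(0:500, 40))
  for (m in c(5, 17, 30)) {
    expect_equal(
      volume_surrogate(rp, boundary_annotation("r", 2, 35)),
      volume_surrogate(rp, boundary_annotation("r", 2, m)) +
        volume_surrogate(rp, boundary_annotation("r", m + 1, 35)))
  }
  # widening the interval never decreases the volume
  v <- sapply(10:35, function(e)
    volume_surrogate(rp, boundary_annotation("r", 5, e)))
  expect_true(all(diff(v) >= 0))
})

test_that("enlargement measures positive excess over the chord baseline", {
  lin <- slice_profile("p", seq(100, 200, by = 25))
  expect_equal(enlargement_surrogate(lin, boundary_annotation("p", 0, 4)), 0)
  bump <- slice_profile("p", c(100, 150, 200, 150, 100))
  expect_equal(enlargement_surrogate(bump, boundary_annotation("p", 0, 4)),
               200)  # excesses 0 + 50 + 100 + 50 + 0
  dip <- slice_profile("p", c(100, 40, 180, 40, 100))
  expect_equal(enlargement_surrogate(dip, boundary_annotation("p", 0, 4)),
               80)  # dips below the baseline are clipped to zero
  expect_equal(enlargement_surrogate(bump, boundary_annotation("p", 2, 2)), 0)
})

test_that("classification metrics reproduce the screening confusion matrix", {
  m <- classification_metrics(tp = 15, fp = 2, fn = 2, tn = 14)
  expect_equal(m$accuracy, 87.9)
  expect_equal(m$precision, 88.2)
  expect_equal(m$recall, 88.2)
  expect_equal(m$specificity, 87.5)
  expect_equal(m$f1, 88.2)

  perfect <- classification_metrics(tp = 9, fp = 0, fn = 0, tn = 6)
  expect_true(all(unlist(perfect) == 100))

  half <- classification_metrics(tp = 1, fp = 1, fn = 1, tn = 1)
  expect_equal(half$accuracy, 50)
  expect_equal(half$precision, 50)
  expect_equal(half$f1, 50)

  # zero denominators yield NULL, not NaN
  expect_null(classification_metrics(tp = 0, fp = 0, fn = 2, tn = 3)$precision)
})

test_that("cohort evaluation matches per-patient arithmetic", {
  profs <- lapply(1:3, function(i)
    slice_profile(paste0("P", i), rep(100L, 60) + i))
  anns <- list(boundary_annotation("P1", 10, 30),
               boundary_annotation("P2", 20, 45),
               boundary_annotation("P3", 5, 25))
  coh <- cohort(profs, anns)

  # identical predictions: perfect report
  perfect <- evaluate_cohort(coh, anns)
  expect_equal(perfect$mean_dice, 1)
  expect_equal(perfect$r2_start, 1)
  expect_equal(perfect$r2_end, 1)
  expect_equal(perfect$r2_volume, 1)
  expect_equal(perfect$mae_start, 0)
  expect_equal(perfect$mse_end, 0)
  expect_equal(perfect$n_missed, 0L)

  # known offsets (+2, -3, 0) on both boundaries
  off <- c(2, -3, 0)
  preds <- lapply(1:3, function(i)
    boundary_annotation(paste0("P", i), anns[[i]]$start + off[i],
                        anns[[i]]$end + off[i]))
  rep_off <- evaluate_cohort(coh, preds)
  hand <- mae_mse(c(10, 20, 5), c(10, 20, 5) + off)
  expect_equal(rep_off$mae_start, hand$mae)
  expect_equal(rep_off$mse_start, hand$mse)
  expect_equal(rep_off$mae_end, hand$mae)
  expect_equal(rep_off$mse_end, hand$mse)

  # all-absent predictions: Dice 0, null regressions, everything missed
  none <- lapply(1:3, function(i)
    boundary_annotation(paste0("P", i), present = FALSE))
  rep_none <- evaluate_cohort(coh, none)
  expect_equal(rep_none$mean_dice, 0)
  expect_null(rep_none$r2_start)
  expect_null(rep_none$mae_end)
  expect_equal(rep_none$n_missed, 3L)
  expect_equal(rep_none$n_predicted, 0L)

  expect_error(
    evaluate_cohort(coh, list(boundary_annotation("ZZ", 1, 2))),
    "unknown")
})
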