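test_that("the failure screen reproduces step-through oracle values", {
  cfg <- screen_defaults()  # window 4, 140/50 percent, persistence 4

  flat <- slice_profile("flat", rep(100L, 30))
  expect_equal(screen_failure(flat, cfg)$label, "normal")

  # dropout of six slices: flagged exactly while counts sit below half the
  # held normal baseline, recovery slice is not flagged
  drop6 <- slice_profile("d", c(rep(100L, 10), rep(0L, 6), rep(100L, 10)))
  res <- screen_failure(drop6, cfg)
  expect_equal(res$label, "aneurysm")
  expect_equal(res$first_flagged, 10L)
  expect_equal(res$last_flagged, 15L)

  # two-slice spike is shorter than the persistence requirement
  spike <- slice_profile("s", c(rep(100L, 10), rep(200L, 2), rep(100L, 10)))
  expect_equal(screen_failure(spike, cfg)$label, "normal")

  expect_error(screen_failure(slice_profile("x", rep(5L, 6)), cfg),
               "too short")
})

test_that("screen agrees with the independent oracle on random profiles", {
  cfg <- screen_defaults()
  for (seed in 1:20) {
    prof <- random_rule_profile(paste0("r", seed), seed)
    got <- screen_failure(prof, cfg)
    want <- oracle_screen(prof$counts, cfg$window, cfg$upper, cfg$lower,
                          cfg$persistence)
    expect_equal(got$label, want$label, label = paste("seed", seed))
    if (want$label == "aneurysm") {
      expect_equal(got$first_flagged, want$first)
      expect_equal(got$last_flagged, want$last)
    }
  }
})

test_that("boundary detector finds the largest abnormality region", {
  cfg <- rule_config()  # window 4, 120/80 percent

  expect_false(
    detect_boundaries_expert(slice_profile("f", rep(100L, 50)), cfg)$present)

  # sustained plateau: frozen oracle values from the step-through simulation
  plateau <- slice_profile("p",
                           c(rep(100L, 20), rep(160L, 15), rep(100L, 20)))
  got <- detect_boundaries_expert(plateau, cfg)
  expect_true(got$present)
  expect_equal(got$start, 20L)
  expect_equal(got$end, 34L)

  # agreement with the oracle across random profiles
  for (seed in 21:40) {
    prof <- random_rule_profile(paste0("r", seed), seed)
    got <- detect_boundaries_expert(prof, cfg)
    want <- oracle_detect(prof$counts, cfg$window, cfg$upper, cfg$lower)
    if (is.null(want)) {
      expect_false(got$present, label = paste("seed", seed))
    } else {
      expect_equal(got$start, unname(want["start"]),
                   label = paste("seed", seed))
      expect_equal(got$end, unname(want["end"]))
    }
  }
})

test_that("both rules are invariant to rescaling the counts", {
  cfg_b <- rule_config()
  cfg_s <- screen_defaults()
  for (seed in 41:50) {
    prof <- random_rule_profile(paste0("r", seed), seed)
    # double the base counts so halving keeps them integral
    base <- slice_profile(prof$patient_id, prof$counts * 2L)
    ref_b <- detect_boundaries_expert(base, cfg_b)
    ref_s <- screen_failure(base, cfg_s)
    for (c_scale in c(0.5, 3, 10)) {
      scaled <- slice_profile(base$patient_id, base$counts * c_scale)
      got_b <- detect_boundaries_expert(scaled, cfg_b)
      expect_equal(got_b$present, ref_b$present)
      if (ref_b$present) {
        expect_equal(got_b$start, ref_b$start)
        expect_equal(got_b$end, ref_b$end)
      }
      got_s <- screen_failure(scaled, cfg_s)
      expect_equal(got_s$label, ref_s$label)
      expect_equal(got_s$first_flagged, ref_s$first_flagged)
    }
  }
})

test_that("no detected region extends into the baseline-seeding slices", {
  cfg <- rule_config()
  for (seed in 51:70) {
    prof <- random_rule_profile(paste0("r", seed), seed)
    got <- detect_boundaries_expert(prof, cfg)
    if (got$present) expect_gte(got$start, cfg$window)
  }
  # even an immediate plateau cannot be flagged before slice `window`
  early <- slice_profile("e", c(rep(300L, 2), rep(100L, 40)))
  got <- detect_boundaries_expert(early, cfg)
  if (got$present) expect_gte(got$start, cfg$window)
})

test_that("grid search equals exhaustive evaluation and breaks ties", {
  coh <- generate_cohort(5, 1, synthetic_params(noise_sd_frac = 0.02),
                         seed = 31)
  grid <- grid_spec(windows = c(3, 4, 5), uppers = c(1.1, 1.2, 1.3),
                    lowers = c(0.6, 0.8, 0.9))
  gs <- grid_search(coh, grid)

  # independent exhaustive double loop
  best <- list(obj = -Inf)
  for (w in grid$windows) for (u in grid$uppers) for (l in grid$lowers) {
    cfg <- rule_config(w, u, l)
    dice <- mean(sapply(names(coh$annotations), function(id)
      interval_dice(detect_boundaries_expert(coh$profiles[[id]], cfg),
                    coh$annotations[[id]])))
    better <- dice > best$obj ||
      (dice == best$obj && (w < best$w ||
        (w == best$w && (u < best$u ||
          (u == best$u && l > best$l)))))
    if (better) best <- list(obj = dice, w = w, u = u, l = l)
  }
  expect_equal(gs$objective, best$obj)
  expect_equal(gs$config$window, best$w)
  expect_equal(gs$config$upper, best$u)
  expect_equal(gs$config$lower, best$l)
  # the returned objective dominates every grid point
  expect_true(all(gs$objective >= gs$table$objective))

  # singleton grid returns its only candidate
  single <- grid_search(coh, grid_spec(windows = 4, uppers = 1.2,
                                       lowers = 0.8))
  expect_equal(single$config$window, 4L)
  expect_equal(
    single$objective,
    mean(sapply(names(coh$annotations), function(id)
      interval_dice(detect_boundaries_expert(coh$profiles[[id]],
                                             rule_config(4, 1.2, 0.8)),
                    coh$annotations[[id]]))))

  # all-tied objectives resolve toward the smaller window
  flat <- cohort(list(slice_profile("f", rep(100L, 50))),
                 list(boundary_annotation("f", 10, 20)))
  tie <- grid_search(flat, grid_spec(windows = c(5, 3), uppers = 1.2,
                                     lowers = 0.8))
  expect_equal(tie$config$window, 3L)

  expect_error(grid_search(cohort(list(slice_profile("x", rep(1L, 30)))),
                           grid), "annotated")
})
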