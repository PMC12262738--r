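test_that("contrast stretch maps the input range onto [out_low, out_high]", {
  expect_equal(as.vector(contrast_stretch(matrix(c(0, 1000), 1))),
               c(10L, 245L))
  # hand-evaluated midpoint: 10 + 500 * 235 / 1000 = 127.5, half away -> 128
  expect_equal(as.vector(contrast_stretch(matrix(c(0, 500, 1000), 1))),
               c(10L, 128L, 245L))
  img <- matrix(sample(0:4095, 64), 8, 8)
  out <- contrast_stretch(img)
  expect_equal(min(out), 10L)
  expect_equal(max(out), 245L)
  expect_equal(dim(out), dim(img))
})

test_that("degenerate images stretch deterministically", {
  expect_true(all(contrast_stretch(matrix(77, 3, 3)) == 10L))
  expect_error(contrast_stretch(matrix(numeric(0), 0, 0)), "empty")
})

test_that("contrast stretch is idempotent on its own output", {
  img <- matrix(sample(0:9999, 100), 10, 10)
  once <- contrast_stretch(img)
  expect_equal(contrast_stretch(once), once)
})

test_that("extract_profile counts set pixels per slice", {
  z <- mask_stack("p", array(0L, dim = c(4, 4, 5)))
  expect_equal(extract_profile(z)$counts, rep(0L, 5))

  m <- matrix(0L, 6, 6)
  m[2, c(1, 3, 5)] <- 1L
  m[4, 2:5] <- 1L
  one <- mask_stack("p", array(m, dim = c(6, 6, 1)))
  expect_equal(extract_profile(one)$counts, 7L)
})

test_that("a rendered disk matches brute-force lattice enumeration", {
  grid <- 64L
  radius <- 10
  ctr <- (grid + 1) / 2
  m <- outer(1:grid, 1:grid,
             function(x, y) ((x - ctr)^2 + (y - ctr)^2 <= radius^2) * 1L)
  stack <- mask_stack("p", array(m, dim = c(grid, grid, 1)))
  expect_equal(extract_profile(stack)$counts, disk_pixel_count(grid, radius))
})

test_that("profile extraction is invariant to zero padding the slices", {
  set.seed(4)
  sl <- array(rbinom(5 * 5 * 3, 1, 0.4), dim = c(5, 5, 3))
  padded <- array(0L, dim = c(9, 9, 3))
  padded[3:7, 3:7, ] <- sl
  expect_equal(extract_profile(mask_stack("p", padded))$counts,
               extract_profile(mask_stack("p", sl))$counts)
})

test_that("cohort CSV round-trips are identities", {
  coh <- generate_cohort(3, 2 / 3, synthetic_params(n_slices = 60),
                         seed = 5, halfwidth_range = c(8, 12))
  pfile <- tempfile(fileext = ".csv")
  afile <- tempfile(fileext = ".csv")
  write_cohort(coh, pfile, afile)
  back <- load_cohort(pfile, afile)
  expect_equal(back, coh)

  # loading without annotations still yields all profiles
  prof_only <- load_cohort(pfile)
  expect_equal(length(prof_only$profiles), 3)
  expect_equal(length(prof_only$annotations), 0)
})

test_that("malformed cohort files are rejected with the offending row", {
  pfile <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,slice_index,pixel_count",
               "A,0,100", "A,1,-5"), pfile)
  expect_error(load_cohort(pfile), "negative.*row 2")

  writeLines(c("patient_id,slice_index,pixel_count",
               "A,0,100", "A,0,90"), pfile)
  expect_error(load_cohort(pfile), "duplicate")

  writeLines(c("patient_id,slice_index,pixel_count",
               "A,0,100", "A,2,90"), pfile)
  expect_error(load_cohort(pfile), "contiguous")

  writeLines(c("patient_id,slice_index,pixel_count",
               "A,0,100", "A,1,90", "A,2,90", "A,3,90"), pfile)
  afile <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,start_slice,end_slice,present", "A,3,1,1"), afile)
  expect_error(load_cohort(pfile, afile), "start <= end")
  writeLines(c("patient_id,start_slice,end_slice,present", "B,1,2,1"), afile)
  expect_error(load_cohort(pfile, afile), "no profile")
})

test_that("evaluation reports round-trip through JSON, keeping nulls", {
  rep1 <- eval_report(mean_dice = 0.8, r2_start = 0.7, r2_end = 0.75,
                      r2_volume = 0.9, mae_start = 2, mae_end = 3,
                      mse_start = 8, mse_end = 11, n_predicted = 9,
                      n_missed = 1, detector = "expert")
  f <- tempfile(fileext = ".json")
  save_report(rep1, f)
  expect_equal(read_report(f), rep1)

  # no predictions: regression metrics stay null, not zero
  rep2 <- eval_report(mean_dice = 0, n_predicted = 0, n_missed = 5)
  save_report(rep2, f)
  back <- read_report(f)
  expect_null(back$r2_volume)
  expect_null(back$mae_start)
  expect_equal(back$n_missed, 5L)

  # degenerate empty-cohort report is still a valid file
  rep3 <- eval_report(mean_dice = 0, n_predicted = 0, n_missed = 0)
  save_report(rep3, f)
  expect_equal(read_report(f)$n_predicted, 0L)
})

test_that("mask stacks round-trip through multi-page TIFF", {
  skip_if_not_installed("tiff")
  coh <- generate_cohort(1, 1, synthetic_params(n_slices = 12, baseline = 100),
                         seed = 2, halfwidth_range = c(2, 3))
  stack <- render_mask_stack(coh$profiles[[1]], grid = 64L)
  f <- tempfile(fileext = ".tif")
  write_mask_stack(stack, f)
  back <- read_mask_stack(f, patient_id = stack$patient_id)
  expect_equal(back$slices, stack$slices)
  expect_equal(extract_profile(back)$counts, coh$profiles[[1]]$counts)
})

test_that("mask stacks read from NIfTI volumes", {
  skip_if_not_installed("RNifti")
  arr <- array(0L, dim = c(8, 8, 4))
  arr[3:5, 3:5, 2] <- 1L
  arr[2:6, 2:6, 3] <- 1L
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr * 1.0), f)
  stack <- read_mask_stack(f, patient_id = "n1")
  expect_equal(extract_profile(stack)$counts, c(0L, 9L, 25L, 0L))
})

test_that("invalid profiles and annotations are rejected", {
  expect_error(slice_profile("p", integer(0)), "at least one")
  expect_error(slice_profile("p", c(3, -1)), "non-negative")
  expect_error(boundary_annotation("p", 5, 2), "start <= end")
  expect_error(
    cohort(list(slice_profile("p", rep(10, 5))),
           list(boundary_annotation("p", 2, 7))),
    "beyond profile")
  expect_error(
    cohort(list(slice_profile("p", rep(10, 5))),
           list(boundary_annotation("q", 1, 2))),
    "no profile")
})
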