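#' Parameters for the synthetic profile generator
#'
#' The generator emulates the pixel-count signal of a segmented abdominal
#' aorta: a roughly constant normal caliber with multiplicative noise, an
#' optional linear distal taper toward the iliac bifurcation, and a smooth
#' aneurysmal enlargement modeled as a raised-cosine bump. The raised cosine
#' (rather than, say, a Gaussian) gives the annotated region a closed form:
#' the noiseless bump multiplier is `1 + A * 0.5 * (1 + cos(pi*(i-c)/h))`
#' inside `|i - c| <= h` and 1 outside, and the ground-truth annotation is
#' the contiguous set of slices where that multiplier strictly exceeds
#' `ann_threshold` (1.2 by default, the same relative enlargement the expert
#' rule's start criterion uses, so synthetic truth and the rule are
#' commensurable).
#'
#' With `dropout = TRUE` the counts inside the annotated interval are
#' replaced by near-zero draws, emulating a segmentation model that stops
#' producing masks on pathological slices.
#'
#' @param n_slices Number of axial slices (default 200).
#' @param baseline Mean normal-caliber pixel count (default 300).
#' @param noise_sd_frac Multiplicative Gaussian noise sd as a fraction of
#'   the local mean (default 0.03).
#' @param bump_amplitude_frac Peak excess over baseline as a fraction of
#'   baseline (default 1.0, i.e. the aneurysm peaks at twice normal area);
#'   0 produces a normal profile.
#' @param bump_center Slice index of the bump peak (default mid-profile).
#' @param bump_halfwidth Half-width of the raised cosine in slices
#'   (default 25).
#' @param taper_frac Linear distal decline fraction over the full profile
#'   (default 0.1).
#' @param dropout Emit near-zero counts inside the aneurysm (default
#'   `FALSE`).
#' @param ann_threshold Bump multiplier above which a slice is annotated
#'   aneurysmal (default 1.2).
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_slices = 200L, baseline = 300,
                             noise_sd_frac = 0.03,
                             bump_amplitude_frac = 1.0,
                             bump_center = NULL, bump_halfwidth = 25L,
                             taper_frac = 0.1, dropout = FALSE,
                             ann_threshold = 1.2, seed = 1L) {
  n_slices <- as.integer(n_slices)
  bump_halfwidth <- as.integer(bump_halfwidth)
  if (is.null(bump_center)) bump_center <- n_slices %/% 2L
  bump_center <- as.integer(bump_center)
  stopifnot(n_slices >= 10L, baseline > 0, noise_sd_frac >= 0,
            bump_amplitude_frac >= 0, bump_halfwidth >= 1L,
            taper_frac >= 0, taper_frac < 1, ann_threshold > 1,
            is.logical(dropout), length(dropout) == 1L)
  structure(
    list(n_slices = n_slices, baseline = baseline,
         noise_sd_frac = noise_sd_frac,
         bump_amplitude_frac = bump_amplitude_frac,
         bump_center = bump_center, bump_halfwidth = bump_halfwidth,
         taper_frac = taper_frac, dropout = dropout,
         ann_threshold = ann_threshold, seed = as.integer(seed)),
    class = "synthetic_params"
  )
}

# raised-cosine bump value in [0, 1] at slice i (0-based)
raised_cosine <- function(i, center, halfwidth) {
  d <- abs(i - center)
  ifelse(d <= halfwidth, 0.5 * (1 + cos(pi * (i - center) / halfwidth)), 0)
}

# run a function under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate one synthetic aortic profile with its annotation
#'
#' The noiseless signal is
#' `baseline * (1 - taper_frac * i / n_slices) * (1 + A * rc(i))` where
#' `rc` is the raised cosine of [synthetic_params()]; counts are the signal
#' with multiplicative Gaussian noise, rounded and floored at zero. The
#' annotation marks the slices whose noiseless bump multiplier exceeds the
#' annotation threshold; a zero-amplitude bump yields an absent annotation.
#'
#' @param params A [synthetic_params()].
#' @param patient_id Patient id for the generated objects.
#' @return List with `profile` (a [slice_profile()]) and `annotation`
#'   (a [boundary_annotation()]).
#' @export
generate_profile <- function(params = synthetic_params(),
                             patient_id = "SYN001") {
  stopifnot(inherits(params, "synthetic_params"))
  n <- params$n_slices
  if (params$bump_amplitude_frac > 0 &&
      (params$bump_center - params$bump_halfwidth < 0L ||
       params$bump_center + params$bump_halfwidth >= n)) {
    stop("bump support extends outside the profile", call. = FALSE)
  }
  i <- seq_len(n) - 1L
  mult <- 1 + params$bump_amplitude_frac *
    raised_cosine(i, params$bump_center, params$bump_halfwidth)
  signal <- params$baseline * (1 - params$taper_frac * i / n) * mult
  ann_slices <- which(mult > params$ann_threshold) - 1L

  counts <- with_seed(params$seed, {
    noisy <- signal * (1 + stats::rnorm(n, 0, params$noise_sd_frac))
    cnt <- pmax(0, round_half_away(noisy))
    if (params$dropout && length(ann_slices)) {
      lo <- min(ann_slices) + 1L
      hi <- max(ann_slices) + 1L
      cnt[lo:hi] <- round_half_away(
        stats::runif(hi - lo + 1L, 0, 0.05 * params$baseline))
    }
    cnt
  })

  annotation <- if (length(ann_slices)) {
    boundary_annotation(patient_id, min(ann_slices), max(ann_slices))
  } else {
    boundary_annotation(patient_id, present = FALSE)
  }
  list(profile = slice_profile(patient_id, counts),
       annotation = annotation)
}

#' Generate a segmentation-dropout (failure) profile
#'
#' Convenience wrapper forcing `dropout = TRUE`: inside the annotated
#' aneurysm interval every count is replaced by a uniform draw in
#' `[0, 0.05 * baseline]`, outside it the profile is unchanged. With a
#' zero-amplitude bump there is no interval and the profile equals the
#' normal one.
#'
#' @inheritParams generate_profile
#' @return As [generate_profile()].
#' @export
generate_failure_profile <- function(params = synthetic_params(),
                                     patient_id = "SYN001") {
  stopifnot(inherits(params, "synthetic_params"))
  params$dropout <- TRUE
  generate_profile(params, patient_id)
}

#' Generate a synthetic patient cohort
#'
#' Draws `round(n * aneurysm_fraction)` aneurysmal profiles and fills the
#' remainder with normal ones. For aneurysmal patients the bump amplitude,
#' half-width and center are randomized within `amplitude_range`,
#' `halfwidth_range` and the feasible center positions. The default
#' amplitude range 3-8 reflects a repair-eligible AAA cohort: aneurysms of
#' 4 to 6 cm diameter against a 2 cm normal aorta have cross-sectional areas
#' 4 to 9 times normal, i.e. a peak excess of 3 to 8 times baseline. The
#' default half-width range 15-30 slices corresponds to aneurysm lengths of
#' roughly 5 to 12 cm at 2 mm slice spacing.
#'
#' @param n Number of patients.
#' @param aneurysm_fraction Fraction of patients with an aneurysm
#'   (default 1, mirroring an all-AAA surgical cohort).
#' @param params Template [synthetic_params()]; per-patient seeds and
#'   randomized bump geometry override its `seed`, `bump_center`,
#'   `bump_halfwidth` and `bump_amplitude_frac`.
#' @param seed Cohort-level seed controlling all randomization.
#' @param amplitude_range Numeric length-2 range for the bump amplitude of
#'   aneurysmal patients.
#' @param halfwidth_range Integer length-2 range for the bump half-width.
#' @return An [cohort()] with one annotation per patient (absent for
#'   normals).
#' @export
generate_cohort <- function(n, aneurysm_fraction = 1,
                            params = synthetic_params(), seed = 1L,
                            amplitude_range = c(3, 8),
                            halfwidth_range = c(15L, 30L)) {
  stopifnot(n >= 1, aneurysm_fraction >= 0, aneurysm_fraction <= 1,
            inherits(params, "synthetic_params"))
  n <- as.integer(n)
  n_aneurysm <- as.integer(round(n * aneurysm_fraction))
  ids <- sprintf("SYN%03d", seq_len(n))
  draws <- with_seed(seed, {
    list(
      amplitude = stats::runif(n, amplitude_range[1], amplitude_range[2]),
      halfwidth = as.integer(round(stats::runif(n, halfwidth_range[1],
                                                halfwidth_range[2]))),
      center_u = stats::runif(n),
      seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  profiles <- vector("list", n)
  annotations <- vector("list", n)
  for (k in seq_len(n)) {
    p <- params
    p$seed <- draws$seeds[k]
    if (k <= n_aneurysm) {
      hw <- draws$halfwidth[k]
      # keep the bump support inside the profile with margin for the
      # baseline-seeding slices
      lo <- hw + params$n_slices %/% 10L
      hi <- params$n_slices - 1L - hw - params$n_slices %/% 20L
      if (hi < lo) stop("profile too short for the half-width range",
                        call. = FALSE)
      p$bump_amplitude_frac <- draws$amplitude[k]
      p$bump_halfwidth <- hw
      p$bump_center <- as.integer(lo + round(draws$center_u[k] * (hi - lo)))
    } else {
      p$bump_amplitude_frac <- 0
    }
    out <- generate_profile(p, ids[k])
    profiles[[k]] <- out$profile
    annotations[[k]] <- out$annotation
  }
  cohort(profiles, annotations)
}

#' Render a profile as a stack of disk masks
#'
#' Builds, for each slice, a centered disk-like binary mask containing
#' exactly the profile's pixel count: lattice points are taken in order of
#' distance from the grid center (ties broken deterministically), so
#' [extract_profile()] of the rendered stack reproduces the profile
#' exactly.
#'
#' @param profile A [slice_profile()] whose counts do not exceed `grid^2`.
#' @param grid Side length of the square mask (default 128).
#' @return A [mask_stack()].
#' @export
render_mask_stack <- function(profile, grid = 128L) {
  stopifnot(inherits(profile, "slice_profile"))
  grid <- as.integer(grid)
  if (any(profile$counts > grid * grid)) {
    stop("count exceeds grid area; enlarge `grid`", call. = FALSE)
  }
  ctr <- (grid + 1) / 2
  xs <- rep(seq_len(grid), times = grid)
  ys <- rep(seq_len(grid), each = grid)
  d2 <- (xs - ctr)^2 + (ys - ctr)^2
  ord <- order(d2, xs, ys)  # deterministic tie-break on coordinates
  slices <- array(0L, dim = c(grid, grid, profile$slice_count))
  for (k in seq_len(profile$slice_count)) {
    cnt <- profile$counts[k]
    if (cnt > 0L) {
      sel <- ord[seq_len(cnt)]
      page <- integer(grid * grid)
      page[(ys[sel] - 1L) * grid + xs[sel]] <- 1L
      slices[, , k] <- matrix(page, grid, grid)
    }
  }
  mask_stack(profile$patient_id, slices)
}
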