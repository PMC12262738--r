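#' Per-slice aortic cross-section profile
#'
#' A slice profile is one patient's ordered sequence of segmented-pixel
#' counts, one count per axial slice. It is the 1-D signal every detector in
#' this package consumes: the pixel count of a segmented aortic cross-section
#' is a surrogate for cross-sectional area, so an aneurysm appears as a
#' sustained enlargement of the count.
#'
#' Slice index 0 is the most superior analyzed slice; indices increase toward
#' the iliac bifurcation. All slice indices in this package are 0-based so
#' that profile positions, annotations, and the CSV interchange format agree.
#'
#' @param patient_id Single character string identifying the patient.
#' @param counts Integer vector of non-negative segmented-pixel counts,
#'   length at least 1, ordered superior to inferior.
#' @return An object of class `slice_profile` with fields `patient_id`,
#'   `counts` (integer) and `slice_count`.
#' @examples
#' p <- slice_profile("P001", c(300, 310, 305, 298))
#' p$slice_count
#' @export
slice_profile <- function(patient_id, counts) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            !is.na(patient_id), nzchar(patient_id))
  if (length(counts) < 1L) {
    stop("a slice profile needs at least one slice", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("slice counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("slice counts must be whole numbers of pixels", call. = FALSE)
  }
  structure(
    list(patient_id = patient_id,
         counts = as.integer(round(counts)),
         slice_count = length(counts)),
    class = "slice_profile"
  )
}

#' @export
print.slice_profile <- function(x, ...) {
  cat(sprintf("<slice_profile> patient %s: %d slices, counts %d-%d\n",
              x$patient_id, x$slice_count, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Aneurysm boundary annotation
#'
#' Inclusive start/end slice indices of an aneurysm on a slice profile,
#' either manual ground truth or a detector prediction. Indices are 0-based
#' and both ends are inclusive, matching the surrogate-volume sum over
#' slices `start..end`.
#'
#' @param patient_id Single character string.
#' @param start,end 0-based inclusive slice indices; ignored (and stored as
#'   `NA`) when `present` is `FALSE`.
#' @param present Logical; `FALSE` means no aneurysm and undefined bounds.
#' @return An object of class `boundary_annotation`.
#' @examples
#' boundary_annotation("P001", 40, 80)
#' boundary_annotation("P002", present = FALSE)
#' @export
boundary_annotation <- function(patient_id, start = NA, end = NA,
                                present = TRUE) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.logical(present), length(present) == 1L, !is.na(present))
  if (present) {
    if (is.na(start) || is.na(end)) {
      stop("present annotations need both start and end", call. = FALSE)
    }
    start <- as.integer(start)
    end <- as.integer(end)
    if (start < 0L || start > end) {
      stop(sprintf("invalid boundaries [%d, %d]: need 0 <= start <= end",
                   start, end), call. = FALSE)
    }
  } else {
    start <- NA_integer_
    end <- NA_integer_
  }
  structure(
    list(patient_id = patient_id, start = start, end = end,
         present = present),
    class = "boundary_annotation"
  )
}

#' @export
print.boundary_annotation <- function(x, ...) {
  if (x$present) {
    cat(sprintf("<boundary_annotation> patient %s: slices [%d, %d]\n",
                x$patient_id, x$start, x$end))
  } else {
    cat(sprintf("<boundary_annotation> patient %s: no aneurysm\n",
                x$patient_id))
  }
  invisible(x)
}

#' Binary segmentation mask stack
#'
#' An ordered stack of 2-D binary masks (one per axial slice), all with the
#' same height and width, as produced by a segmentation backend. Values are
#' restricted to 0/1; any nonzero input is treated as mask.
#'
#' @param patient_id Single character string.
#' @param slices 3-D array `(height, width, n_slices)` or a list of equally
#'   sized binary matrices.
#' @return An object of class `mask_stack` with a 3-D integer array `slices`.
#' @export
mask_stack <- function(patient_id, slices) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (is.list(slices)) {
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L || is.null(dims[[1]])) {
      stop("all mask slices must be matrices of identical dimensions",
           call. = FALSE)
    }
    slices <- array(unlist(slices, use.names = FALSE),
                    dim = c(dims[[1]], length(slices)))
  }
  if (!is.array(slices) || length(dim(slices)) != 3L) {
    stop("slices must form a height x width x n_slices array", call. = FALSE)
  }
  if (anyNA(slices)) stop("mask values must not be missing", call. = FALSE)
  slices <- array(as.integer(slices != 0), dim = dim(slices))
  structure(list(patient_id = patient_id, slices = slices),
            class = "mask_stack")
}

#' Patient cohort of profiles and annotations
#'
#' Bundles one slice profile per patient with (optionally) one boundary
#' annotation per patient. Every annotation must refer to an existing
#' profile, and a present annotation must fit inside its profile.
#'
#' @param profiles List of [slice_profile()] objects.
#' @param annotations Optional list of [boundary_annotation()] objects.
#' @return An object of class `aaa_cohort`: named lists `profiles` and
#'   `annotations`, both keyed by patient id.
#' @examples
#' coh <- cohort(list(slice_profile("P1", rep(300, 50))),
#'               list(boundary_annotation("P1", 10, 20)))
#' length(coh$profiles)
#' @export
cohort <- function(profiles, annotations = list()) {
  stopifnot(is.list(profiles), is.list(annotations))
  ids <- vapply(profiles, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id among profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(profiles) <- ids
  ann_ids <- vapply(annotations, function(a) a$patient_id, character(1))
  if (anyDuplicated(ann_ids)) {
    stop("duplicate patient_id among annotations", call. = FALSE)
  }
  missing <- setdiff(ann_ids, ids)
  if (length(missing)) {
    stop("annotations refer to patients with no profile: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  names(annotations) <- ann_ids
  for (a in annotations) {
    if (a$present && a$end >= profiles[[a$patient_id]]$slice_count) {
      stop(sprintf("annotation for %s ends at slice %d beyond profile (%d slices)",
                   a$patient_id, a$end, profiles[[a$patient_id]]$slice_count),
           call. = FALSE)
    }
  }
  structure(list(profiles = profiles, annotations = annotations),
            class = "aaa_cohort")
}

#' @export
print.aaa_cohort <- function(x, ...) {
  n_pos <- sum(vapply(x$annotations, function(a) a$present, logical(1)))
  cat(sprintf("<aaa_cohort> %d profiles, %d annotations (%d aneurysmal)\n",
              length(x$profiles), length(x$annotations), n_pos))
  invisible(x)
}

# number of patients in a cohort
cohort_size <- function(cohort) length(cohort$profiles)

#' Subset a cohort by patient id
#'
#' @param cohort An [cohort()] object.
#' @param ids Character vector of patient ids to keep.
#' @return A new `aaa_cohort` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  missing <- setdiff(ids, names(cohort$profiles))
  if (length(missing)) {
    stop("unknown patient ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(profiles = cohort$profiles[ids],
         annotations = cohort$annotations[intersect(ids, names(cohort$annotations))]),
    class = "aaa_cohort"
  )
}
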