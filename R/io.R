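#' Linear contrast stretch to 8-bit range
#'
#' Affinely maps the intensity range `[min(image), max(image)]` onto
#' `[out_low, out_high]` and rounds half away from zero, the normalization
#' applied to CTA slices before segmentation. A constant image has no
#' stretchable range and maps every pixel to `out_low`.
#'
#' @param image Non-empty matrix (or array) of non-negative intensities.
#' @param out_low,out_high Output range bounds, defaults 10 and 245.
#' @return Integer array of the same shape with values in
#'   `[out_low, out_high]`.
#' @examples
#' contrast_stretch(matrix(c(0, 500, 1000), 1))
#' @export
contrast_stretch <- function(image, out_low = 10L, out_high = 245L) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (anyNA(image)) stop("image contains missing values", call. = FALSE)
  stopifnot(out_low < out_high)
  lo <- min(image)
  hi <- max(image)
  out <- if (hi == lo) {
    array(rep(out_low, length(image)), dim = dim(image) %||% length(image))
  } else {
    scaled <- out_low + (image - lo) * (out_high - out_low) / (hi - lo)
    round_half_away(scaled)
  }
  storage.mode(out) <- "integer"
  out
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a pixel-count profile from a mask stack
#'
#' Counts the segmented (1-valued) pixels on every slice of a binary mask
#' stack, producing the 1-D area-surrogate signal the boundary detectors
#' operate on.
#'
#' @param stack A [mask_stack()].
#' @return A [slice_profile()] with one count per slice, order preserved.
#' @export
extract_profile <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  counts <- apply(stack$slices, 3, sum)
  slice_profile(stack$patient_id, counts)
}

#' Read a binary mask stack from TIFF or NIfTI
#'
#' Reads a multi-page TIFF (one page per axial slice) or a NIfTI volume and
#' binarizes it (any nonzero value is mask). Requires the `tiff` or `RNifti`
#' package respectively.
#'
#' @param path Path to a `.tif`/`.tiff` or `.nii`/`.nii.gz` file.
#' @param patient_id Patient id to attach; defaults to the file stem.
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(patient_id)) {
    patient_id <- sub("\\.(tif|tiff|nii|nii\\.gz)$", "",
                      basename(path), ignore.case = TRUE)
  }
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF stacks requires the 'tiff' package", call. = FALSE)
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # readTIFF returns floats in [0,1]; keep a single channel if multi-channel
    pages <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      (pg != 0) * 1L
    })
    mask_stack(patient_id, pages)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI volumes requires the 'RNifti' package",
           call. = FALSE)
    }
    vol <- RNifti::readNifti(path)
    vol <- as.array(vol)
    if (length(dim(vol)) != 3L) {
      stop("expected a 3-D NIfTI volume", call. = FALSE)
    }
    mask_stack(patient_id, vol != 0)
  } else {
    stop("unsupported mask format (use .tif/.tiff or .nii/.nii.gz): ", path,
         call. = FALSE)
  }
}

#' Write a mask stack as a multi-page TIFF
#'
#' @param stack A [mask_stack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mask_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF stacks requires the 'tiff' package", call. = FALSE)
  }
  n <- dim(stack$slices)[3]
  pages <- lapply(seq_len(n), function(i) stack$slices[, , i] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Load a cohort from profile and annotation CSV files
#'
#' The profiles file has columns `patient_id,slice_index,pixel_count` with
#' 0-based contiguous slice indices per patient. The optional annotations
#' file has columns `patient_id,start_slice,end_slice,present` with `present`
#' in `{0,1}` and empty start/end when `present = 0`.
#'
#' @param profiles_path Path to the profiles CSV.
#' @param annotations_path Optional path to the annotations CSV.
#' @return An [cohort()].
#' @export
load_cohort <- function(profiles_path, annotations_path = NULL) {
  prof <- utils::read.csv(profiles_path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "slice_index", "pixel_count")
  if (!all(needed %in% names(prof))) {
    stop("profiles CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(prof$slice_index) || anyNA(prof$pixel_count)) {
    bad <- which(is.na(prof$slice_index) | is.na(prof$pixel_count))[1]
    stop(sprintf("malformed profile row %d (missing value)", bad),
         call. = FALSE)
  }
  if (any(prof$pixel_count < 0)) {
    bad <- which(prof$pixel_count < 0)[1]
    stop(sprintf("negative pixel count in profile row %d (patient %s, slice %d)",
                 bad, prof$patient_id[bad], prof$slice_index[bad]),
         call. = FALSE)
  }
  dup <- duplicated(prof[c("patient_id", "slice_index")])
  if (any(dup)) {
    bad <- which(dup)[1]
    stop(sprintf("duplicate (patient_id, slice_index) at profile row %d (%s, %d)",
                 bad, prof$patient_id[bad], prof$slice_index[bad]),
         call. = FALSE)
  }
  profiles <- lapply(split(prof, prof$patient_id), function(d) {
    d <- d[order(d$slice_index), ]
    if (!identical(as.integer(d$slice_index), seq_len(nrow(d)) - 1L)) {
      stop(sprintf("slice indices for patient %s are not 0-based contiguous",
                   d$patient_id[1]), call. = FALSE)
    }
    slice_profile(d$patient_id[1], d$pixel_count)
  })
  annotations <- list()
  if (!is.null(annotations_path)) {
    ann <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
    needed <- c("patient_id", "start_slice", "end_slice", "present")
    if (!all(needed %in% names(ann))) {
      stop("annotations CSV must have columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    annotations <- lapply(seq_len(nrow(ann)), function(i) {
      row <- ann[i, ]
      if (!row$present %in% c(0L, 1L)) {
        stop(sprintf("annotation row %d: present must be 0 or 1", i),
             call. = FALSE)
      }
      if (row$present == 1L) {
        if (is.na(row$start_slice) || is.na(row$end_slice)) {
          stop(sprintf("annotation row %d: present=1 but boundaries missing", i),
               call. = FALSE)
        }
        boundary_annotation(row$patient_id, row$start_slice, row$end_slice)
      } else {
        boundary_annotation(row$patient_id, present = FALSE)
      }
    })
  }
  cohort(unname(profiles), annotations)
}

#' Write a cohort to profile and annotation CSV files
#'
#' Inverse of [load_cohort()]; writing then loading reproduces the cohort.
#'
#' @param cohort An [cohort()].
#' @param profiles_path Output path for the profiles CSV.
#' @param annotations_path Optional output path for the annotations CSV.
#' @return `profiles_path`, invisibly.
#' @export
write_cohort <- function(cohort, profiles_path, annotations_path = NULL) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  prof <- do.call(rbind, lapply(cohort$profiles, function(p) {
    data.frame(patient_id = p$patient_id,
               slice_index = seq_len(p$slice_count) - 1L,
               pixel_count = p$counts)
  }))
  utils::write.csv(prof, profiles_path, row.names = FALSE, quote = FALSE)
  if (!is.null(annotations_path)) {
    ann <- do.call(rbind, lapply(cohort$annotations, function(a) {
      data.frame(patient_id = a$patient_id,
                 start_slice = if (a$present) a$start else NA_integer_,
                 end_slice = if (a$present) a$end else NA_integer_,
                 present = as.integer(a$present))
    }))
    if (is.null(ann)) {
      ann <- data.frame(patient_id = character(), start_slice = integer(),
                        end_slice = integer(), present = integer())
    }
    utils::write.csv(ann, annotations_path, row.names = FALSE, quote = FALSE)
  }
  invisible(profiles_path)
}

#' Save an evaluation report as JSON
#'
#' Writes every report field, preserving `NULL` metrics (metrics that were
#' undefined, e.g. boundary regressions when nothing was predicted) as JSON
#' `null` rather than coercing them to 0.
#'
#' @param report An `eval_report` from [evaluate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  fields <- unclass(report)
  num <- vapply(fields, is.numeric, logical(1))
  if (any(vapply(fields[num], function(v) any(!is.finite(v)), logical(1)))) {
    stop("report contains non-finite values", call. = FALSE)
  }
  jsonlite::write_json(fields, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an evaluation report written by [save_report()]
#'
#' @param path JSON path.
#' @return An `eval_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(eval_report, x)
}
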