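#' Bidirectional LSTM detector architecture
#'
#' The slice labeler: stacked bidirectional LSTM layers read the normalized
#' pixel-count sequence in both directions, a small fully connected stack
#' with ReLU activations (shared across timesteps) maps each timestep's
#' concatenated hidden state to one score, and a sigmoid yields a per-slice
#' aneurysm probability over `output_len` positions. Slices at or above
#' `threshold` are classified aneurysmal.
#'
#' The full-scale configuration is two stacked bidirectional layers of 600
#' hidden units per direction with fully connected widths 256 and 64 over
#' 200 output positions. Simulation studies in the tests and vignette use a
#' smaller `hidden_units` for speed; the architecture is otherwise
#' identical.
#'
#' @param recurrent_layers Number of stacked bidirectional layers
#'   (default 2).
#' @param hidden_units Hidden units per layer per direction (default 600).
#' @param fc_hidden Integer vector of fully connected hidden widths
#'   (default `c(256, 64)`).
#' @param output_len Sequence length the network operates on (default 200);
#'   shorter profiles are zero-padded, longer ones truncated distally.
#' @param threshold Per-slice classification threshold in (0, 1),
#'   default 0.5.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(recurrent_layers = 2L, hidden_units = 600L,
                          fc_hidden = c(256L, 64L), output_len = 200L,
                          threshold = 0.5) {
  stopifnot(recurrent_layers >= 1, hidden_units >= 1, output_len >= 1,
            threshold > 0, threshold < 1, all(fc_hidden >= 1))
  structure(
    list(recurrent_layers = as.integer(recurrent_layers),
         hidden_units = as.integer(hidden_units),
         fc_hidden = as.integer(fc_hidden),
         output_len = as.integer(output_len),
         threshold = threshold),
    class = "detector_spec"
  )
}

#' LSTM training configuration
#'
#' Optimization protocol for the slice labeler: Adam with learning rate
#' 0.0003 and batch size 10, minimizing binary cross-entropy plus a
#' weighted soft-Jaccard term, with early stopping on validation loss.
#'
#' @param learning_rate Adam step size (default 0.0003).
#' @param batch_size Profiles per gradient step (default 10).
#' @param max_epochs Upper bound on training epochs (default 1000).
#' @param jaccard_weight Weight of the `1 - soft-Jaccard` loss term
#'   (default 1).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 100).
#' @param seed Seed controlling weight init and batch order.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 3e-4, batch_size = 10L,
                            max_epochs = 1000L, jaccard_weight = 1,
                            early_stop_patience = 100L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            jaccard_weight >= 0, early_stop_patience >= 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         jaccard_weight = jaccard_weight,
         early_stop_patience = as.integer(early_stop_patience),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Encode an annotation as a per-slice binary target
#'
#' Element `i` (0-based) is 1 exactly when the annotation is present and
#' `start <= i <= end`.
#'
#' @param ann A [boundary_annotation()].
#' @param length Output vector length; a present annotation must end before
#'   it.
#' @return Numeric 0/1 vector of `length`.
#' @export
encode_labels <- function(ann, length) {
  stopifnot(inherits(ann, "boundary_annotation"), length >= 1)
  y <- numeric(length)
  if (ann$present) {
    if (ann$end >= length) {
      stop(sprintf("annotation end %d does not fit in length %d",
                   ann$end, length), call. = FALSE)
    }
    y[(ann$start + 1L):(ann$end + 1L)] <- 1
  }
  y
}

#' Normalize and pad a profile for the network
#'
#' Counts are divided by the profile's maximum count (an all-zero profile
#' maps to zeros with scale 1, avoiding division by zero) and zero-padded
#' at the distal end to `length`. Profiles longer than `length` are
#' truncated at the distal end with a warning. Per-profile max scaling
#' preserves the relative enlargement geometry (the 120/80 percent
#' structure) that carries the aneurysm signal.
#'
#' @param profile A [slice_profile()].
#' @param length Network input length (default 200).
#' @return List with `x` (numeric vector of `length`), `scale` (the
#'   divisor, allowing count reconstruction) and `n_used` (profile slices
#'   represented, at most `length`).
#' @export
prepare_input <- function(profile, length = 200L) {
  stopifnot(inherits(profile, "slice_profile"), length >= 1)
  counts <- profile$counts
  if (profile$slice_count > length) {
    warning(sprintf("profile %s has %d slices; truncating distally to %d",
                    profile$patient_id, profile$slice_count, length))
    counts <- counts[seq_len(length)]
  }
  scale <- max(counts)
  if (scale == 0) scale <- 1
  x <- numeric(length)
  x[seq_along(counts)] <- counts / scale
  list(x = x, scale = scale, n_used = length(counts))
}

# canonical parameter list for the C++ core; uniform init in
# [-1/sqrt(h), 1/sqrt(h)] with forget-gate biases at +1 so memory is
# retained early in training
init_lstm_params <- function(spec, input_dim = 1L) {
  h <- spec$hidden_units
  k <- 1 / sqrt(h)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  params <- list()
  d <- input_dim
  for (l in seq_len(spec$recurrent_layers)) {
    for (dir in 1:2) {
      b <- rmat(1L, 4L * h)
      b[1, (h + 1L):(2L * h)] <- 1
      params <- c(params, list(rmat(d, 4L * h), rmat(h, 4L * h), b))
    }
    d <- 2L * h
  }
  widths <- c(2L * h, spec$fc_hidden, 1L)
  for (j in seq_len(length(widths) - 1L)) {
    kj <- 1 / sqrt(widths[j])
    params <- c(params, list(
      matrix(stats::runif(widths[j] * widths[j + 1L], -kj, kj),
             widths[j], widths[j + 1L]),
      matrix(0, 1L, widths[j + 1L])))
  }
  params
}

# stack a cohort into network matrices (one row per patient)
build_dataset <- function(cohort, spec) {
  ids <- names(cohort$profiles)
  miss <- setdiff(ids, names(cohort$annotations))
  if (length(miss)) {
    stop("profiles without annotations: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  len <- spec$output_len
  X <- matrix(0, length(ids), len)
  Y <- matrix(0, length(ids), len)
  n_used <- integer(length(ids))
  for (k in seq_along(ids)) {
    inp <- prepare_input(cohort$profiles[[ids[k]]], len)
    X[k, ] <- inp$x
    n_used[k] <- inp$n_used
    Y[k, ] <- encode_labels(cohort$annotations[[ids[k]]], len)
  }
  list(X = X, Y = Y, ids = ids, n_used = n_used)
}

#' Train the bidirectional LSTM slice labeler
#'
#' Minimizes mean `BCE + jaccard_weight * (1 - soft-Jaccard)` between the
#' per-slice probabilities and the binary aneurysm-interval targets with
#' Adam, recording train and validation loss each epoch. The parameters
#' achieving the best validation loss are restored at the end, and training
#' stops early after `early_stop_patience` epochs without validation
#' improvement. Train and validation cohorts must not share patients.
#'
#' @param train,validation Annotated [cohort()]s with disjoint patients.
#' @param spec A [detector_spec()].
#' @param cfg A [training_config()].
#' @param verbose Print a progress line every 25 epochs.
#' @return An object of class `trained_detector`: `spec`, `cfg`, `params`
#'   (weights at the best validation loss), `loss_history` (data.frame with
#'   epoch, train, validation), and `best_epoch`.
#' @export
train_detector <- function(train, validation, spec = detector_spec(),
                           cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(train, "aaa_cohort"),
            inherits(validation, "aaa_cohort"),
            inherits(spec, "detector_spec"),
            inherits(cfg, "training_config"))
  overlap <- intersect(names(train$profiles), names(validation$profiles))
  if (length(overlap)) {
    stop("patient leakage between train and validation: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  tr <- build_dataset(train, spec)
  va <- build_dataset(validation, spec)
  n <- nrow(tr$X)

  with_seed(cfg$seed, {
    params <- init_lstm_params(spec)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_val <- Inf
    best_params <- params
    best_epoch <- 0L
    since_best <- 0L
    hist_train <- hist_val <- numeric(0)

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        res <- .lstm_core(tr$X[idx, , drop = FALSE],
                          tr$Y[idx, , drop = FALSE],
                          params, spec$recurrent_layers, spec$hidden_units,
                          cfg$jaccard_weight, TRUE)
        step <- step + 1L
        lr_t <- cfg$learning_rate *
          sqrt(1 - beta2^step) / (1 - beta1^step)
        for (j in seq_along(params)) {
          g <- res$grads[[j]]
          m[[j]] <- beta1 * m[[j]] + (1 - beta1) * g
          v[[j]] <- beta2 * v[[j]] + (1 - beta2) * g * g
          params[[j]] <- params[[j]] - lr_t * m[[j]] / (sqrt(v[[j]]) + eps)
        }
        batch_losses <- c(batch_losses, res$loss)
      }
      val <- .lstm_core(va$X, va$Y, params, spec$recurrent_layers,
                        spec$hidden_units, cfg$jaccard_weight, FALSE)
      hist_train <- c(hist_train, mean(batch_losses))
      hist_val <- c(hist_val, val$loss)
      if (val$loss < best_val) {
        best_val <- val$loss
        best_params <- params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (verbose && epoch %% 25L == 0L) {
        message(sprintf("epoch %4d  train %.4f  val %.4f (best %.4f @%d)",
                        epoch, mean(batch_losses), val$loss, best_val,
                        best_epoch))
      }
      if (since_best >= cfg$early_stop_patience) break
    }

    structure(
      list(spec = spec, cfg = cfg, params = best_params,
           loss_history = data.frame(epoch = seq_along(hist_train),
                                     train = hist_train,
                                     validation = hist_val),
           best_epoch = best_epoch),
      class = "trained_detector"
    )
  })
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf(
    "<trained_detector> %d x biLSTM(%d), fc [%s], %d epochs (best %d), val loss %.4f\n",
    x$spec$recurrent_layers, x$spec$hidden_units,
    paste(x$spec$fc_hidden, collapse = ", "), nrow(x$loss_history),
    x$best_epoch, min(x$loss_history$validation)))
  invisible(x)
}

#' Predict aneurysm boundaries with a trained detector
#'
#' Runs the network on the prepared profile and decodes the per-slice
#' probabilities: positions at or above the spec's threshold form candidate
#' runs, the longest run (ties broken toward the earliest) gives the
#' boundaries, and padding positions beyond the profile are excluded. With
#' no position above threshold the annotation is absent.
#'
#' @param model A `trained_detector` from [train_detector()].
#' @param profile A [slice_profile()].
#' @return List with `annotation` (a [boundary_annotation()]) and
#'   `probabilities` (per-slice vector over the profile's represented
#'   slices).
#' @export
predict_boundaries <- function(model, profile) {
  stopifnot(inherits(model, "trained_detector"),
            inherits(profile, "slice_profile"))
  inp <- prepare_input(profile, model$spec$output_len)
  res <- .lstm_core(matrix(inp$x, 1L), matrix(0, 1L, model$spec$output_len),
                    model$params, model$spec$recurrent_layers,
                    model$spec$hidden_units, 0, FALSE)
  probs <- as.numeric(res$probs)[seq_len(inp$n_used)]
  ann <- decode_probabilities(probs, model$spec$threshold,
                              profile$patient_id)
  list(annotation = ann, probabilities = probs)
}

# longest run at or above threshold -> boundary annotation (0-based)
decode_probabilities <- function(probs, threshold, patient_id) {
  runs <- true_runs(probs >= threshold)
  if (nrow(runs) == 0L) {
    return(boundary_annotation(patient_id, present = FALSE))
  }
  best <- runs[order(-runs$length, runs$start)[1], ]
  boundary_annotation(patient_id, best$start - 1L, best$end - 1L)
}

#' Patient-level k-fold cross-validation of the LSTM detector
#'
#' Patients are partitioned once (seeded) into `k` disjoint folds. For each
#' fold the detector is trained on the remaining patients — with a slice of
#' them (default 15 percent) carved off as the early-stopping validation
#' set — and evaluated on the fold's untouched test patients. No patient
#' ever appears on both sides of a fold.
#'
#' @param cohort An annotated [cohort()] with at least `k` patients.
#' @param k Number of folds (default 5, i.e. 80/20 splits).
#' @param spec A [detector_spec()].
#' @param cfg A [training_config()]; its seed fixes the fold assignment.
#' @param val_fraction Fraction of each fold's training patients used for
#'   early stopping (default 0.15).
#' @param verbose Passed to [train_detector()].
#' @return List with `folds` (per-fold [eval_report()]s), `pooled` (fold
#'   metrics averaged, `NULL`s ignored), `assignments` (named fold index
#'   per patient) and `models` (the per-fold `trained_detector`s).
#' @export
cross_validate <- function(cohort, k = 5L, spec = detector_spec(),
                           cfg = training_config(), val_fraction = 0.15,
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  ids <- names(cohort$profiles)
  if (k > length(ids)) {
    stop(sprintf("k = %d exceeds the %d patients available", k,
                 length(ids)), call. = FALSE)
  }
  assignments <- assign_folds(ids, k, cfg$seed)
  folds <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- ids[assignments == f]
    pool_ids <- ids[assignments != f]
    n_val <- max(1L, ceiling(val_fraction * length(pool_ids)))
    val_ids <- with_seed(cfg$seed + f, sample(pool_ids, n_val))
    train_ids <- setdiff(pool_ids, val_ids)
    stopifnot(length(intersect(train_ids, test_ids)) == 0L,
              length(intersect(val_ids, test_ids)) == 0L)
    model <- train_detector(subset_cohort(cohort, train_ids),
                            subset_cohort(cohort, val_ids),
                            spec, cfg, verbose = verbose)
    preds <- lapply(test_ids, function(id) {
      predict_boundaries(model, cohort$profiles[[id]])$annotation
    })
    folds[[f]] <- evaluate_cohort(subset_cohort(cohort, test_ids), preds,
                                  detector = sprintf("lstm fold %d", f))
    models[[f]] <- model
  }
  list(folds = folds, pooled = pool_reports(folds, "lstm pooled"),
       assignments = assignments, models = models)
}

# seeded patient-level fold assignment: every patient lands in exactly one
# test fold, fold sizes differ by at most one
assign_folds <- function(ids, k, seed) {
  with_seed(seed, {
    fold <- rep(seq_len(k), length.out = length(ids))
    stats::setNames(sample(fold), ids)
  })
}

# average numeric fields across reports, ignoring NULLs; counts are summed
pool_reports <- function(reports, detector = "pooled") {
  fields <- c("mean_dice", "r2_start", "r2_end", "r2_volume",
              "mae_start", "mae_end", "mse_start", "mse_end")
  pooled <- lapply(fields, function(f) {
    vals <- unlist(lapply(reports, function(r) r[[f]]))
    if (length(vals)) mean(vals) else NULL
  })
  names(pooled) <- fields
  do.call(eval_report, c(pooled, list(
    n_predicted = sum(vapply(reports, function(r) r$n_predicted, integer(1))),
    n_missed = sum(vapply(reports, function(r) r$n_missed, integer(1))),
    detector = detector)))
}

#' Save or load a trained detector
#'
#' The archive is a single RDS file holding the spec, training config,
#' weights and loss history.
#'
#' @param model A `trained_detector`.
#' @param path Archive path.
#' @return `path` (save) or the `trained_detector` (load).
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "trained_detector"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_detector"))
  model
}
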