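# Subject-wise cross-validated training with plateau learning-rate decay
# and early stopping. Subject leakage between train and validation windows
# is a protocol violation and is asserted on every run.

#' Training configuration
#'
#' @param batch_size Mini-batch size.
#' @param lr0 Starting learning rate (Adam).
#' @param max_epochs Epoch ceiling.
#' @param plateau_factor Multiplier applied to the learning rate when the
#'   validation loss plateaus (`0 < factor < 1`).
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is scaled.
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts.
#' @param min_delta Absolute validation-MAE decrease that counts as an
#'   improvement.
#' @param seed Seed controlling weight init warm start and batch shuffles.
#' @param warm_start_bias Initialize the scalar output bias at the
#'   training-set mean RR before the first epoch (gradient-trained
#'   estimators only).
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 256L, lr0 = 1e-3, max_epochs = 1000L,
                         plateau_factor = 0.1, plateau_patience = 10L,
                         early_stop_patience = 50L, min_delta = 1e-3,
                         seed = 1L, warm_start_bias = TRUE) {
  if (!(plateau_factor > 0 && plateau_factor < 1)) {
    stop("require 0 < plateau_factor < 1", call. = FALSE)
  }
  if (plateau_patience < 1L || early_stop_patience < 1L) {
    stop("patience values must be >= 1", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = seed,
                 warm_start_bias = isTRUE(warm_start_bias)),
            class = "train_config")
}

#' Subject-wise k-fold partition
#'
#' Shuffles the subject IDs and partitions them into `k` near-equal
#' validation sets (sizes differing by at most one), so every subject
#' appears in exactly one fold's validation set and no subject ever
#' contributes windows to both sides of a fold.
#'
#' @param ids Character vector of subject IDs (deduplicated).
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of `fold_split` objects with fields `fold_index`
#'   (0-based), `train_ids`, `val_ids`.
#' @export
make_subject_folds <- function(ids, k = 5L, seed = 1L) {
  ids <- unique(as.character(ids))
  if (length(ids) < k) {
    stop(sprintf("split error: %d subjects cannot form %d folds",
                 length(ids), k), call. = FALSE)
  }
  shuffled <- .with_seed(seed, sample(ids))
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- cumsum(c(0L, sizes))
  lapply(seq_len(k), function(i) {
    val <- shuffled[(bounds[i] + 1L):bounds[i + 1L]]
    structure(list(fold_index = i - 1L,
                   train_ids = setdiff(shuffled, val),
                   val_ids = val),
              class = "fold_split")
  })
}

#' Withdraw a per-group test set of subjects
#'
#' Assigns each record's subject to a breathing group by its mean
#' reference RR over the whole recording, then withdraws the requested
#' number of subjects per group into a test set (seeded draw).
#'
#' @param records List of [ppg_record()]s.
#' @param n_per_group Named counts, e.g. `c(slow = 1, normal = 3,
#'   rapid = 3)`.
#' @param seed Draw seed.
#' @return `list(train = records, test = records)`.
#' @export
split_test_by_group <- function(records, n_per_group, seed = 1L) {
  stopifnot(length(records) > 0)
  groups <- vapply(records, function(r)
    assign_group(rr_label_for_interval(r, 0, r$duration_s)), character(1))
  wanted <- c(slow = 0, normal = 0, rapid = 0)
  wanted[names(n_per_group)] <- n_per_group
  test_idx <- .with_seed(seed, {
    unlist(lapply(names(wanted), function(g) {
      pool <- which(groups == g)
      if (length(pool) < wanted[[g]]) {
        stop(sprintf(
          "split error: %d '%s' subjects available but %d requested",
          length(pool), g, wanted[[g]]), call. = FALSE)
      }
      if (wanted[[g]] == 0) integer(0) else
        pool[sample.int(length(pool), wanted[[g]])]
    }))
  })
  list(train = records[setdiff(seq_along(records), test_idx)],
       test = records[test_idx])
}

.assert_no_leakage <- function(train_ids, val_ids) {
  common <- intersect(unique(train_ids), unique(val_ids))
  if (length(common) > 0) {
    stop(sprintf(
      "protocol violation: subject(s) %s appear in both train and validation sets",
      paste(common, collapse = ", ")), call. = FALSE)
  }
}

#' Train an estimator with plateau decay and early stopping
#'
#' Runs [fit_epoch()] epochs with Adam at `lr0`. When the validation MAE
#' fails to improve by `min_delta` for `plateau_patience` consecutive
#' epochs, the learning rate is multiplied by `plateau_factor` (an exact
#' x0.1 step at defaults). Training halts after `early_stop_patience`
#' epochs without improvement or at `max_epochs`; the weights of the best
#' validation epoch are returned.
#'
#' @param est An estimator ([build_dilated_resnet()], [build_baseline()],
#'   or any object with [fit_epoch()] and [predict()] methods).
#' @param train_windows,val_windows `window_set`s with disjoint subject
#'   sets (asserted).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return `list(estimator, history, best_epoch, best_val_mae)`; `history`
#'   is a data.frame with `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
train_estimator <- function(est, train_windows, val_windows,
                            cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(train_windows, "window_set"),
            inherits(val_windows, "window_set"),
            inherits(cfg, "train_config"))
  .assert_no_leakage(train_windows$meta$subject_id,
                     val_windows$meta$subject_id)
  x <- train_windows$x
  y <- train_windows$meta$rr_true
  .with_seed(cfg$seed, {
    if (cfg$warm_start_bias && !isTRUE(est$trained) &&
        !is.null(est$params$head$dense2$b)) {
      est$params$head$dense2$b <- mean(y)
    }
    lr <- cfg$lr0
    best_val <- Inf
    best_est <- est
    best_epoch <- 0L
    since_best <- 0L
    since_plateau <- 0L
    history <- vector("list", cfg$max_epochs)
    n_done <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      step <- fit_epoch(est, x, y, lr, cfg$batch_size)
      est <- step$est
      val_pred <- predict(est, val_windows)
      val_mae <- mae(val_windows$meta$rr_true, val_pred)
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = step$loss,
                                     val_loss = val_mae, lr = lr)
      n_done <- epoch
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %g",
                        epoch, step$loss, val_mae, lr))
      }
      if (val_mae < best_val - cfg$min_delta) {
        best_val <- val_mae
        best_est <- est
        best_epoch <- epoch
        since_best <- 0L
        since_plateau <- 0L
      } else {
        since_best <- since_best + 1L
        since_plateau <- since_plateau + 1L
        if (since_best >= cfg$early_stop_patience) break
        if (since_plateau >= cfg$plateau_patience) {
          lr <- lr * cfg$plateau_factor
          since_plateau <- 0L
        }
      }
    }
    best_est$trained <- TRUE
    list(estimator = best_est,
         history = do.call(rbind, history[seq_len(n_done)]),
         best_epoch = best_epoch,
         best_val_mae = best_val)
  })
}

#' Subject-wise k-fold cross-validation of an estimator family
#'
#' Builds one fresh estimator per fold with `build_fn`, trains it on the
#' fold's training subjects and evaluates on its validation subjects.
#'
#' @param build_fn Zero-argument function returning an untrained
#'   estimator.
#' @param windows A `window_set` covering all subjects.
#' @param k Number of folds.
#' @param cfg A [train_config()].
#' @param seed Fold-shuffle seed.
#' @param verbose Passed to [train_estimator()].
#' @return `list(folds, fold_maes, estimators, histories)`.
#' @export
cross_validate <- function(build_fn, windows, k = 5L, cfg = train_config(),
                           seed = 1L, verbose = FALSE) {
  folds <- make_subject_folds(unique(windows$meta$subject_id), k, seed)
  fits <- lapply(folds, function(fold) {
    tr <- subset_windows(windows, windows$meta$subject_id %in% fold$train_ids)
    va <- subset_windows(windows, windows$meta$subject_id %in% fold$val_ids)
    train_estimator(build_fn(), tr, va, cfg, verbose = verbose)
  })
  list(folds = folds,
       fold_maes = vapply(fits, `[[`, numeric(1), "best_val_mae"),
       estimators = lapply(fits, `[[`, "estimator"),
       histories = lapply(fits, `[[`, "history"))
}
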