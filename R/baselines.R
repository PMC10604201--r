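# Simplified reference baselines behind the common estimator interface.
#
# These are deliberately lightweight stand-ins for the published
# architectures they are named after: each is a fixed, seeded feature
# extractor (convolutional, recurrent, or encoder-decoder) followed by a
# trainable linear readout fitted in closed form (ridge regression). They
# honor the estimator contract -- deterministic predict given weights, a
# fit hook, a name, a layer summary -- and the stated layer widths
# (LSTM 256, CNN-LSTM 256, BiLSTM 128 per direction, attention BiLSTM 64
# per direction), without re-implementing the third-party training
# recipes.

.baseline_names <- c("resnet", "lstm", "cnn_lstm", "bilstm",
                     "attn_bilstm", "unet_regressor")

#' Build a simplified reference baseline estimator
#'
#' @param name One of `"resnet"`, `"lstm"`, `"cnn_lstm"`, `"bilstm"`,
#'   `"attn_bilstm"`, `"unet_regressor"`.
#' @param cfg Optional list: `input_len` (default 1800), `seed` (default
#'   1), `ridge` (readout penalty, default 1e-3), `seq_pool` (pre-pooling
#'   width before recurrent layers, default 8).
#' @return An estimator of class
#'   `c(name, "ppgrr_head_estimator", "ppgrr_estimator")`.
#' @export
build_baseline <- function(name, cfg = list()) {
  if (!name %in% .baseline_names) {
    stop(sprintf("configuration error: unknown baseline '%s'; choices are %s",
                 name, paste(.baseline_names, collapse = ", ")),
         call. = FALSE)
  }
  input_len <- cfg$input_len %||% 1800L
  seed <- cfg$seed %||% 1L
  est <- .with_seed(seed, switch(
    name,
    resnet = .arch_resnet(input_len),
    lstm = .arch_lstm(input_len, units = 256L,
                      seq_pool = cfg$seq_pool %||% 8L),
    cnn_lstm = .arch_cnn_lstm(input_len, units = 256L),
    bilstm = .arch_bilstm(input_len, units = 128L, attention = FALSE,
                          seq_pool = cfg$seq_pool %||% 8L),
    attn_bilstm = .arch_bilstm(input_len, units = 64L, attention = TRUE,
                               seq_pool = cfg$seq_pool %||% 8L),
    unet_regressor = .arch_unet(input_len)
  ))
  est$name <- name
  est$input_len <- input_len
  est$ridge <- cfg$ridge %||% 1e-3
  est$head <- list(w = numeric(est$n_features), b = 0)
  est$trained <- FALSE
  class(est) <- c(name, "ppgrr_head_estimator", "ppgrr_estimator")
  est
}

.rand_conv <- function(F, C, k) .init_conv(F, C, k)

.rand_lstm <- function(H, D) {
  list(Wx = matrix(rnorm(4 * H * D, 0, sqrt(1 / D)), 4 * H, D),
       Wh = matrix(rnorm(4 * H * H, 0, sqrt(1 / H)), 4 * H, H),
       b = numeric(4 * H), H = H)
}

.arch_resnet <- function(input_len) {
  F <- 64L
  list(arch = list(stem = .rand_conv(F, 1L, 7L),
                   blocks = lapply(1:2, function(i)
                     list(conv1 = .rand_conv(F, F, 3L),
                          conv2 = .rand_conv(F, F, 3L)))),
       n_features = F,
       layers = data.frame(
         layer = c("conv_stem (stride 2)", "res_block_1", "res_block_2",
                   "global_avg_pool", "dense (RR output)"),
         type = c("conv", "residual_conv", "residual_conv", "pool", "dense"),
         width = c(F, F, F, F, 1L)))
}

.arch_lstm <- function(input_len, units, seq_pool) {
  list(arch = list(lstm = .rand_lstm(units, 1L), seq_pool = seq_pool),
       n_features = units,
       layers = data.frame(
         layer = c(sprintf("avg_pool (width %d)", seq_pool),
                   "lstm", "dense (RR output)"),
         type = c("pool", "recurrent", "dense"),
         width = c(1L, units, 1L)))
}

.arch_cnn_lstm <- function(input_len, units) {
  Fc <- 32L
  list(arch = list(conv = .rand_conv(Fc, 1L, 5L), conv_stride = 4L,
                   pool = 4L, lstm = .rand_lstm(units, Fc)),
       n_features = units,
       layers = data.frame(
         layer = c("conv (stride 4)", "avg_pool (width 4)", "lstm",
                   "dense (RR output)"),
         type = c("conv", "pool", "recurrent", "dense"),
         width = c(Fc, Fc, units, 1L)))
}

.arch_bilstm <- function(input_len, units, attention, seq_pool) {
  arch <- list(fwd = .rand_lstm(units, 1L), bwd = .rand_lstm(units, 1L),
               seq_pool = seq_pool, attention = attention)
  n_feat <- 2L * units
  if (attention) {
    arch$attn <- list(W = matrix(rnorm(n_feat * n_feat, 0, sqrt(1 / n_feat)),
                                 n_feat, n_feat),
                      v = rnorm(n_feat, 0, sqrt(1 / n_feat)))
  }
  layers <- data.frame(
    layer = c(sprintf("avg_pool (width %d)", seq_pool),
              "lstm_forward", "lstm_backward",
              if (attention) "additive_attention",
              "dense (RR output)"),
    type = c("pool", "recurrent", "recurrent",
             if (attention) "attention", "dense"),
    width = c(1L, units, units, if (attention) n_feat, 1L))
  list(arch = arch, n_features = n_feat, layers = layers)
}

.arch_unet <- function(input_len) {
  list(arch = list(enc1 = .rand_conv(16L, 1L, 3L),
                   enc2 = .rand_conv(32L, 16L, 3L),
                   mid = .rand_conv(64L, 32L, 3L),
                   dec2 = .rand_conv(32L, 96L, 3L),
                   dec1 = .rand_conv(16L, 48L, 3L)),
       n_features = 16L,
       layers = data.frame(
         layer = c("enc_conv_1", "down_pool_1", "enc_conv_2", "down_pool_2",
                   "bottleneck_conv", "up_1 + skip", "dec_conv_2",
                   "up_2 + skip", "dec_conv_1", "global_avg_pool",
                   "dense (RR output)"),
         type = c("conv", "pool", "conv", "pool", "conv", "upsample",
                  "conv", "upsample", "conv", "pool", "dense"),
         width = c(16L, 16L, 32L, 32L, 64L, 64L, 32L, 32L, 16L, 16L, 1L)))
}

# ---- forward feature extraction ------------------------------------------

.to_cube <- function(x) array(t(x), dim = c(1L, ncol(x), nrow(x)))

.upsample2 <- function(x, target_len) {
  # linear upsampling of a (C, L, N) cube along time to target_len
  C <- dim(x)[1]; L <- dim(x)[2]; N <- dim(x)[3]
  t_in <- seq(0, 1, length.out = L)
  t_out <- seq(0, 1, length.out = target_len)
  out <- array(0, dim = c(C, target_len, N))
  for (n in seq_len(N)) for (c in seq_len(C)) {
    out[c, , n] <- approx(t_in, x[c, , n], xout = t_out)$y
  }
  out
}

.baseline_features <- function(est, x) {
  switch(est$name,
         resnet = .feats_resnet(est, x),
         lstm = .feats_lstm(est, x),
         cnn_lstm = .feats_cnn_lstm(est, x),
         bilstm = .bilstm_feats(est, x),
         attn_bilstm = .bilstm_feats(est, x),
         unet_regressor = .feats_unet(est, x))
}

.feats_resnet <- function(est, x) {
  xc <- .to_cube(x)
  a <- est$arch
  h <- .cpp_relu_fw(.conv_fw(xc, a$stem, dil = 1L, stride = 2L))
  for (blk in a$blocks) {
    z <- .conv_fw(.cpp_relu_fw(.conv_fw(h, blk$conv1)), blk$conv2)
    h <- .cpp_relu_fw(z + h)
  }
  t(.cpp_gap_fw(h))
}

.lstm_run <- function(xm, lstm) .cpp_lstm_fw(xm, lstm$Wx, lstm$Wh, lstm$b)

.feats_lstm <- function(est, x) {
  xc <- .cpp_avgpool_fw(.to_cube(x), est$arch$seq_pool)
  t(vapply(seq_len(dim(xc)[3]), function(n) {
    hs <- .lstm_run(matrix(xc[1, , n], 1L), est$arch$lstm)
    hs[, ncol(hs)]
  }, numeric(est$n_features)))
}

.feats_cnn_lstm <- function(est, x) {
  a <- est$arch
  h <- .cpp_relu_fw(.conv_fw(.to_cube(x), a$conv, dil = 1L,
                             stride = a$conv_stride))
  h <- .cpp_avgpool_fw(h, a$pool)
  t(vapply(seq_len(dim(h)[3]), function(n) {
    hs <- .lstm_run(h[, , n], a$lstm)
    hs[, ncol(hs)]
  }, numeric(est$n_features)))
}

.bilstm_feats <- function(est, x) {
  a <- est$arch
  xc <- .cpp_avgpool_fw(.to_cube(x), a$seq_pool)
  t(vapply(seq_len(dim(xc)[3]), function(n) {
    xm <- matrix(xc[1, , n], 1L)
    hf <- .lstm_run(xm, a$fwd)
    hb <- .lstm_run(xm[, rev(seq_len(ncol(xm))), drop = FALSE], a$bwd)
    hs <- rbind(hf, hb[, rev(seq_len(ncol(hb))), drop = FALSE])
    if (isTRUE(a$attention)) {
      e <- drop(crossprod(tanh(a$attn$W %*% hs), a$attn$v))
      alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
      drop(hs %*% alpha)
    } else {
      c(hf[, ncol(hf)], hb[, ncol(hb)])
    }
  }, numeric(est$n_features)))
}

.feats_unet <- function(est, x) {
  a <- est$arch
  e1 <- .cpp_relu_fw(.conv_fw(.to_cube(x), a$enc1))
  p1 <- .cpp_avgpool_fw(e1, 2L)
  e2 <- .cpp_relu_fw(.conv_fw(p1, a$enc2))
  p2 <- .cpp_avgpool_fw(e2, 2L)
  m <- .cpp_relu_fw(.conv_fw(p2, a$mid))
  u2 <- .upsample2(m, dim(e2)[2])
  d2 <- .cpp_relu_fw(.conv_fw(.cube_cat(u2, e2), a$dec2))
  u1 <- .upsample2(d2, dim(e1)[2])
  d1 <- .cpp_relu_fw(.conv_fw(.cube_cat(u1, e1), a$dec1))
  t(.cpp_gap_fw(d1))
}

.cube_cat <- function(a, b) {
  stopifnot(dim(a)[2] == dim(b)[2], dim(a)[3] == dim(b)[3])
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# ---- estimator interface --------------------------------------------------

#' @export
predict.ppgrr_head_estimator <- function(object, newdata, ...) {
  x <- .as_window_matrix(newdata)
  feats <- .baseline_features(object, x)
  drop(feats %*% object$head$w) + object$head$b
}

#' @export
fit_epoch.ppgrr_head_estimator <- function(est, x, y, lr, batch_size = 256L) {
  key <- paste(nrow(x), ncol(x), sum(x[1, ]), sep = "|")
  if (is.null(est$feat_cache) || !identical(est$feat_cache$key, key)) {
    est$feat_cache <- list(key = key, f = .baseline_features(est, x))
  }
  f <- est$feat_cache$f
  fm <- colMeans(f); ym <- mean(y)
  fc <- sweep(f, 2L, fm)
  A <- crossprod(fc) + diag(est$ridge, ncol(f))
  w <- solve(A, crossprod(fc, y - ym))
  est$head <- list(w = drop(w), b = ym - sum(fm * w))
  pred <- drop(f %*% est$head$w) + est$head$b
  list(est = est, loss = mean(abs(pred - y)))
}

#' Layer summary for a baseline estimator
#' @param object A baseline estimator from [build_baseline()].
#' @param ... Unused.
#' @return Invisibly, a data.frame with `layer`, `type`, `width`.
#' @export
summary.ppgrr_head_estimator <- function(object, ...) {
  cat(sprintf("Baseline estimator '%s' (%d readout features)\n",
              object$name, object$n_features))
  print(object$layers, row.names = FALSE)
  invisible(object$layers)
}
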