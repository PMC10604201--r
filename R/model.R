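# Dilated residual 1-D regressor.
#
# The network is a stack of RespBlocks. One RespBlock sends its input
# through three parallel branches of dilated 1-D convolutions (each branch
# is two identical dilated conv layers, ReLU after each), then sums the
# three branch outputs together with the channel-wise mean of the block
# input broadcast across filters -- a residual shortcut that needs no
# projection weights. Each stage follows its RespBlock with a stride-2
# downsampling convolution and an average pooling, and doubles the filter
# count of the next stage. The head is global average pooling, one hidden
# dense layer and a scalar linear output emitting RR in brpm.

#' Dilated ResNet hyperparameter configuration
#'
#' The seven tunable hyperparameters with their admissible integer ranges
#' (number of RespBlocks 1-5, block kernel 2-5, dilation 1-5, downsample
#' kernel 2-4, filter exponent 4-10 so base filters are `2^filters_c`,
#' pooling stride 2-4, first dense width 20-100), plus the input geometry.
#' Defaults are the selected values of the reference architecture.
#'
#' @param n_blk Number of RespBlock stages.
#' @param kernel_blk Kernel size of the convolutions inside a RespBlock.
#' @param d_blk Dilation rate of those convolutions.
#' @param kernel_dwn Kernel size of the downsampling convolution.
#' @param filters_c Filter-count exponent; stage s uses
#'   `2^(filters_c + s - 1)` filters.
#' @param s_c Average-pooling width/stride.
#' @param n_den Units of the first dense layer.
#' @param input_len Window length in samples (1800 at pipeline defaults).
#' @param input_channels Input channels (1 for a raw PPG window).
#' @return A `dilated_resnet_config` object.
#' @export
dilated_resnet_config <- function(n_blk = 4L, kernel_blk = 2L, d_blk = 3L,
                                  kernel_dwn = 3L, filters_c = 8L,
                                  s_c = 2L, n_den = 86L,
                                  input_len = 1800L, input_channels = 1L) {
  cfg <- list(n_blk = as.integer(n_blk), kernel_blk = as.integer(kernel_blk),
              d_blk = as.integer(d_blk), kernel_dwn = as.integer(kernel_dwn),
              filters_c = as.integer(filters_c), s_c = as.integer(s_c),
              n_den = as.integer(n_den), input_len = as.integer(input_len),
              input_channels = as.integer(input_channels))
  box <- .drn_search_box()
  for (nm in names(box)) {
    v <- cfg[[nm]]
    if (v < box[[nm]][1] || v > box[[nm]][2]) {
      stop(sprintf("configuration error: %s = %d outside admissible range [%d, %d]",
                   nm, v, box[[nm]][1], box[[nm]][2]), call. = FALSE)
    }
  }
  if (cfg$input_len < 1L || cfg$input_channels < 1L) {
    stop("configuration error: input geometry must be positive", call. = FALSE)
  }
  structure(cfg, class = "dilated_resnet_config")
}

.drn_search_box <- function() {
  list(n_blk = c(1L, 5L), kernel_blk = c(2L, 5L), d_blk = c(1L, 5L),
       kernel_dwn = c(2L, 4L), filters_c = c(4L, 10L), s_c = c(2L, 4L),
       n_den = c(20L, 100L))
}

# per-stage geometry; NULL when the input is too short to survive the
# downsamplings
.drn_lengths <- function(cfg, input_len = cfg$input_len) {
  L <- input_len
  stages <- vector("list", cfg$n_blk)
  for (s in seq_len(cfg$n_blk)) {
    C_in <- if (s == 1L) cfg$input_channels else 2L^(cfg$filters_c + s - 2L)
    F_s <- 2L^(cfg$filters_c + s - 1L)
    L_block <- L
    L_down <- ceiling(L_block / 2)
    L_pool <- L_down %/% cfg$s_c
    if (L_pool < 1L) return(NULL)
    stages[[s]] <- list(C_in = C_in, F = F_s, L_in = L_block,
                        L_down = L_down, L_pool = L_pool)
    L <- L_pool
  }
  stages
}

.drn_min_input_len <- function(cfg) {
  lo <- 1L; hi <- 1L
  while (is.null(.drn_lengths(cfg, hi))) hi <- hi * 2L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (is.null(.drn_lengths(cfg, mid))) lo <- mid + 1L else hi <- mid
  }
  lo
}

.he_init <- function(dim, fan_in) {
  array(rnorm(prod(dim), 0, sqrt(2 / fan_in)), dim = dim)
}

.init_conv <- function(F, C, k) {
  list(W = .he_init(c(F, C, k), C * k), b = numeric(F))
}

#' Build a Dilated ResNet estimator
#'
#' Creates the estimator with seeded He-style weight initialization
#' (biases zero), ready for [train_estimator()]. The stage filter counts
#' double per stage starting at `2^filters_c`.
#'
#' @param cfg A [dilated_resnet_config()].
#' @param seed Seed for the weight initialization.
#' @return An estimator of class `c("dilated_resnet", "ppgrr_estimator")`.
#' @export
build_dilated_resnet <- function(cfg = dilated_resnet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "dilated_resnet_config"))
  geom <- .drn_lengths(cfg)
  if (is.null(geom)) {
    stop(sprintf(
      "configuration error: input_len = %d too short for %d downsampling stages; minimum admissible length is %d",
      cfg$input_len, cfg$n_blk,
      .drn_min_input_len(cfg)), call. = FALSE)
  }
  params <- .with_seed(seed, {
    stages <- lapply(geom, function(g) {
      list(
        branches = lapply(1:3, function(b) list(
          conv1 = .init_conv(g$F, g$C_in, cfg$kernel_blk),
          conv2 = .init_conv(g$F, g$F, cfg$kernel_blk)
        )),
        down = .init_conv(g$F, g$F, cfg$kernel_dwn)
      )
    })
    C_last <- geom[[cfg$n_blk]]$F
    list(stages = stages,
         head = list(
           dense1 = list(W = .he_init(c(cfg$n_den, C_last), C_last),
                         b = numeric(cfg$n_den)),
           dense2 = list(W = .he_init(c(1L, cfg$n_den), cfg$n_den),
                         b = numeric(1L))
         ))
  })
  structure(list(name = "dilated_resnet", cfg = cfg, params = params,
                 geom = geom, opt = NULL, trained = FALSE, seed = seed),
            class = c("dilated_resnet", "ppgrr_estimator"))
}

# ---- low-level wrappers ---------------------------------------------------

.same_pads <- function(k, dil, stride, L) {
  span <- (k - 1L) * dil
  if (stride == 1L) {
    pad <- span
  } else {
    L_out <- ceiling(L / stride)
    pad <- max(0L, (L_out - 1L) * stride + span + 1L - L)
  }
  c(pad %/% 2L, pad - pad %/% 2L)
}

.conv_fw <- function(x, layer, dil = 1L, stride = 1L) {
  p <- .same_pads(dim(layer$W)[3], dil, stride, dim(x)[2])
  y <- .cpp_conv1d_fw(x, layer$W, layer$b, dil, stride, p[1], p[2])
  attr(y, "pads") <- p
  y
}

.conv_bw <- function(x, layer, dy, dil, stride, pads) {
  .cpp_conv1d_bw(x, layer$W, dy, dil, stride, pads[1], pads[2])
}

.bcast_mean <- function(x, F) {
  m <- colMeans(x, dims = 1)            # length x batch
  array(rep(m, each = F), dim = c(F, dim(x)[2], dim(x)[3]))
}

#' RespBlock forward pass
#'
#' Standalone application of one RespBlock to a multi-channel sequence:
#' three parallel branches of two identical dilated convolutions (ReLU
#' after each), summed with the channel-wise mean of the input broadcast
#' across the block's filters. Same-padding preserves sequence length.
#'
#' @param x Array `(channels, length, batch)`.
#' @param weights Block weights, e.g. from [init_resp_block()]:
#'   `list(branches = list(list(conv1 = list(W, b), conv2 = list(W, b)),
#'   ...))`.
#' @param d_blk Dilation rate.
#' @return Array `(filters, length, batch)`.
#' @export
resp_block <- function(x, weights, d_blk = 3L) {
  F <- dim(weights$branches[[1]]$conv1$W)[1]
  if (dim(weights$branches[[1]]$conv1$W)[2] != dim(x)[1]) {
    stop(sprintf("shape error: block expects %d input channels, got %d",
                 dim(weights$branches[[1]]$conv1$W)[2], dim(x)[1]),
         call. = FALSE)
  }
  acc <- .bcast_mean(x, F)
  for (br in weights$branches) {
    h <- .cpp_relu_fw(.conv_fw(x, br$conv1, dil = d_blk))
    h <- .cpp_relu_fw(.conv_fw(h, br$conv2, dil = d_blk))
    acc <- acc + h
  }
  acc
}

#' Initialize RespBlock weights
#'
#' @param C_in Input channels.
#' @param F Filters.
#' @param kernel_blk Kernel size.
#' @param seed Seed for the He-style draw.
#' @return Weight list consumable by [resp_block()].
#' @export
init_resp_block <- function(C_in, F, kernel_blk = 2L, seed = 1L) {
  .with_seed(seed, list(branches = lapply(1:3, function(b) list(
    conv1 = .init_conv(F, C_in, kernel_blk),
    conv2 = .init_conv(F, F, kernel_blk)
  ))))
}

# ---- full network forward / backward --------------------------------------

.drn_forward <- function(params, cfg, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", cfg$n_blk) else NULL
  for (s in seq_len(cfg$n_blk)) {
    st <- params$stages[[s]]
    blk_in <- x
    F <- dim(st$branches[[1]]$conv1$W)[1]
    acc <- .bcast_mean(blk_in, F)
    br_cache <- if (keep_cache) vector("list", 3L) else NULL
    for (b in 1:3) {
      br <- st$branches[[b]]
      h1 <- .conv_fw(blk_in, br$conv1, dil = cfg$d_blk)
      a1 <- .cpp_relu_fw(h1)
      h2 <- .conv_fw(a1, br$conv2, dil = cfg$d_blk)
      a2 <- .cpp_relu_fw(h2)
      acc <- acc + a2
      if (keep_cache) {
        br_cache[[b]] <- list(a1 = a1, a2 = a2,
                              p1 = attr(h1, "pads"), p2 = attr(h2, "pads"))
      }
    }
    hd <- .conv_fw(acc, st$down, dil = 1L, stride = 2L)
    ad <- .cpp_relu_fw(hd)
    pooled <- .cpp_avgpool_fw(ad, cfg$s_c)
    if (keep_cache) {
      caches[[s]] <- list(blk_in = blk_in, branches = br_cache,
                          blk_out = acc, ad = ad, pd = attr(hd, "pads"),
                          L_down = dim(ad)[2])
    }
    x <- pooled
  }
  g <- .cpp_gap_fw(x)                       # channels x batch
  z1 <- params$head$dense1$W %*% g + params$head$dense1$b
  a1 <- pmax(z1, 0)
  out <- drop(params$head$dense2$W %*% a1 + params$head$dense2$b)
  if (keep_cache) {
    list(out = out,
         cache = list(stages = caches, g = g, a1 = a1,
                      L_last = dim(x)[2]))
  } else {
    list(out = out)
  }
}

.drn_backward <- function(params, cfg, cache, dout) {
  N <- length(dout)
  grads <- params  # same skeleton, values overwritten
  dz2 <- matrix(dout, 1L, N)
  grads$head$dense2$W <- dz2 %*% t(cache$a1)
  grads$head$dense2$b <- sum(dz2)
  da1 <- t(params$head$dense2$W) %*% dz2
  dz1 <- da1 * (cache$a1 > 0)
  grads$head$dense1$W <- dz1 %*% t(cache$g)
  grads$head$dense1$b <- rowSums(dz1)
  dg <- t(params$head$dense1$W) %*% dz1
  dx <- .cpp_gap_bw(dg, cache$L_last)

  for (s in rev(seq_len(cfg$n_blk))) {
    st <- params$stages[[s]]
    cs <- cache$stages[[s]]
    dad <- .cpp_avgpool_bw(dx, cfg$s_c, cs$L_down)
    dhd <- .cpp_relu_bw(cs$ad, dad)
    down_bw <- .conv_bw(cs$blk_out, st$down, dhd, dil = 1L, stride = 2L,
                        pads = cs$pd)
    grads$stages[[s]]$down$W <- down_bw$dW
    grads$stages[[s]]$down$b <- down_bw$db
    dacc <- down_bw$dx

    C_in <- dim(cs$blk_in)[1]
    dmean <- colSums(dacc, dims = 1) / C_in      # length x batch
    dblk_in <- array(rep(dmean, each = C_in), dim = dim(cs$blk_in))
    for (b in 1:3) {
      br <- st$branches[[b]]
      bc <- cs$branches[[b]]
      dh2 <- .cpp_relu_bw(bc$a2, dacc)
      bw2 <- .conv_bw(bc$a1, br$conv2, dh2, dil = cfg$d_blk, stride = 1L,
                      pads = bc$p2)
      grads$stages[[s]]$branches[[b]]$conv2$W <- bw2$dW
      grads$stages[[s]]$branches[[b]]$conv2$b <- bw2$db
      dh1 <- .cpp_relu_bw(bc$a1, bw2$dx)
      bw1 <- .conv_bw(cs$blk_in, br$conv1, dh1, dil = cfg$d_blk, stride = 1L,
                      pads = bc$p1)
      grads$stages[[s]]$branches[[b]]$conv1$W <- bw1$dW
      grads$stages[[s]]$branches[[b]]$conv1$b <- bw1$db
      dblk_in <- dblk_in + bw1$dx
    }
    dx <- dblk_in
  }
  grads
}

# ---- flat parameter vector utilities (Adam works on one vector) -----------

.flatten <- function(p) unlist(p, use.names = FALSE)

.unflatten <- function(flat, skel) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(s)
    out
  }
  walk(skel)
}

.adam_step <- function(theta, grad, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# ---- estimator interface --------------------------------------------------

.as_window_matrix <- function(newdata) {
  if (inherits(newdata, "window_set")) newdata$x
  else if (is.matrix(newdata)) newdata
  else matrix(newdata, nrow = 1L)
}

#' Predict RR for preprocessed windows
#'
#' @param object A `dilated_resnet` estimator.
#' @param newdata A `window_set` or a numeric matrix (windows in rows).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Numeric vector of RR estimates in brpm, one per window.
#' @export
predict.dilated_resnet <- function(object, newdata, batch_size = 256L, ...) {
  x <- .as_window_matrix(newdata)
  if (ncol(x) != object$cfg$input_len) {
    stop(sprintf("shape error: windows have %d samples, model expects %d",
                 ncol(x), object$cfg$input_len), call. = FALSE)
  }
  n <- nrow(x)
  out <- numeric(n)
  fused <- object$cfg$input_channels == 1L
  theta <- if (fused) .flatten(object$params)
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(n, i0 + batch_size - 1L)
    xb <- x[i0:i1, , drop = FALSE]
    out[i0:i1] <- if (fused) {
      .cpp_drn_predict(theta, unclass(object$cfg), xb)
    } else {
      .drn_forward(object$params, object$cfg,
                   array(t(xb), dim = c(object$cfg$input_channels,
                                        object$cfg$input_len, nrow(xb))))$out
    }
  }
  out
}

#' One training epoch (generic)
#'
#' Performs one pass over the training windows and returns the updated
#' estimator plus the epoch's mean training loss. Implemented for the
#' gradient-trained estimators; [train_estimator()] drives it.
#'
#' @param est Estimator object.
#' @param x Numeric matrix of training windows (rows).
#' @param y Numeric vector of RR targets in brpm.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @return `list(est = updated estimator, loss = mean training MAE)`.
#' @export
fit_epoch <- function(est, x, y, lr, batch_size = 256L) {
  UseMethod("fit_epoch")
}

#' @export
fit_epoch.dilated_resnet <- function(est, x, y, lr, batch_size = 256L) {
  n <- nrow(x)
  theta <- .flatten(est$params)
  if (is.null(est$opt)) {
    est$opt <- list(m = numeric(length(theta)), v = numeric(length(theta)),
                    t = 0L)
  }
  fused <- est$cfg$input_channels == 1L
  idx <- sample.int(n)
  total_loss <- 0
  for (i0 in seq(1L, n, by = batch_size)) {
    take <- idx[i0:min(n, i0 + batch_size - 1L)]
    nb <- length(take)
    xb <- x[take, , drop = FALSE]
    if (fused) {
      step <- .cpp_drn_fw_bw(theta, unclass(est$cfg), xb, y[take])
      total_loss <- total_loss + step$loss * nb
      grad <- step$grad
    } else {
      xc <- array(t(xb), dim = c(est$cfg$input_channels,
                                 est$cfg$input_len, nb))
      fw <- .drn_forward(.unflatten(theta, est$params), est$cfg, xc,
                         keep_cache = TRUE)
      err <- fw$out - y[take]
      total_loss <- total_loss + sum(abs(err))
      grad <- .flatten(.drn_backward(.unflatten(theta, est$params), est$cfg,
                                     fw$cache, sign(err) / nb))
    }
    upd <- .adam_step(theta, grad, est$opt, lr)
    theta <- upd$theta
    est$opt <- upd$state
  }
  est$params <- .unflatten(theta, est$params)
  list(est = est, loss = total_loss / n)
}

#' @export
print.ppgrr_estimator <- function(x, ...) {
  cat(sprintf("<ppgrr estimator: %s>%s\n", x$name,
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Layer-by-layer model summary
#'
#' @param object A `dilated_resnet` estimator.
#' @param ... Unused.
#' @return Invisibly, a data.frame with columns `layer`, `output_shape`,
#'   `params`; printed with the total parameter count.
#' @export
summary.dilated_resnet <- function(object, ...) {
  cfg <- object$cfg
  rows <- list(data.frame(
    layer = "input",
    output_shape = sprintf("(%d, %d)", cfg$input_channels, cfg$input_len),
    params = 0L))
  count_conv <- function(l) length(l$W) + length(l$b)
  for (s in seq_len(cfg$n_blk)) {
    g <- object$geom[[s]]
    st <- object$params$stages[[s]]
    blk_par <- sum(vapply(st$branches, function(br)
      count_conv(br$conv1) + count_conv(br$conv2), numeric(1)))
    rows <- c(rows, list(
      data.frame(layer = sprintf("resp_block_%d (filters=%d)", s, g$F),
                 output_shape = sprintf("(%d, %d)", g$F, g$L_in),
                 params = blk_par),
      data.frame(layer = sprintf("down_conv_%d (stride 2)", s),
                 output_shape = sprintf("(%d, %d)", g$F, g$L_down),
                 params = count_conv(st$down)),
      data.frame(layer = sprintf("avg_pool_%d (width %d)", s, cfg$s_c),
                 output_shape = sprintf("(%d, %d)", g$F, g$L_pool),
                 params = 0L)))
  }
  C_last <- object$geom[[cfg$n_blk]]$F
  h <- object$params$head
  rows <- c(rows, list(
    data.frame(layer = "global_avg_pool",
               output_shape = sprintf("(%d)", C_last), params = 0L),
    data.frame(layer = sprintf("dense_1 (%d)", cfg$n_den),
               output_shape = sprintf("(%d)", cfg$n_den),
               params = length(h$dense1$W) + length(h$dense1$b)),
    data.frame(layer = "dense_2 (RR output)",
               output_shape = "(1)",
               params = length(h$dense2$W) + length(h$dense2$b))))
  df <- do.call(rbind, rows)
  cat(sprintf("Dilated ResNet: %d stages, %s total parameters\n",
              cfg$n_blk, format(sum(df$params), big.mark = ",")))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Total trainable parameter count
#' @param est An estimator with a `params` field.
#' @return Integer parameter count.
#' @export
model_param_count <- function(est) length(.flatten(est$params))

#' Export a model summary as JSON
#'
#' @param est A `dilated_resnet` estimator.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
model_summary_json <- function(est, path) {
  df <- NULL
  utils::capture.output(df <- summary(est))
  jsonlite::write_json(
    list(name = est$name, total_params = sum(df$params), layers = df),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load estimator checkpoints
#'
#' Checkpoints carry the full estimator (configuration, weights, optimizer
#' state) in R's portable serialization format.
#'
#' @param est Estimator to save.
#' @param path Checkpoint path.
#' @return `save_checkpoint` invisibly returns `path`;
#'   `load_checkpoint` returns the estimator.
#' @export
save_checkpoint <- function(est, path) {
  saveRDS(est, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  }
  readRDS(path)
}
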