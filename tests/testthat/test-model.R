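tiny_cfg <- function(...) {
  args <- list(n_blk = 2L, filters_c = 4L, n_den = 20L, input_len = 120L)
  args[names(list(...))] <- list(...)
  do.call(dilated_resnet_config, args)
}

test_that("hyperparameter configuration enforces the admissible boxes", {
  cfg <- dilated_resnet_config()
  expect_equal(unlist(cfg[c("n_blk", "kernel_blk", "d_blk", "kernel_dwn",
                            "filters_c", "s_c", "n_den")]),
               c(n_blk = 4L, kernel_blk = 2L, d_blk = 3L, kernel_dwn = 3L,
                 filters_c = 8L, s_c = 2L, n_den = 86L))
  expect_error(dilated_resnet_config(n_blk = 6), "n_blk")
  expect_error(dilated_resnet_config(filters_c = 3), "filters_c")
  expect_error(dilated_resnet_config(n_den = 200), "n_den")
})

test_that("stage filters double from 2^filters_c and the summary counts
           parameters", {
  est <- build_dilated_resnet(dilated_resnet_config(), seed = 1)
  expect_equal(vapply(est$geom, `[[`, numeric(1), "F"),
               c(256, 512, 1024, 2048))
  df <- NULL
  capture.output(df <- summary(est))
  expect_equal(sum(df$params), model_param_count(est))
  expect_true(any(grepl("resp_block_4", df$layer)))
  dir <- withr::local_tempdir()
  model_summary_json(est, file.path(dir, "summary.json"))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$total_params, model_param_count(est))
})

test_that("a RespBlock reduces to the broadcast channel mean when its
           convolutions vanish", {
  set.seed(1)
  x <- array(rnorm(3 * 50 * 2), dim = c(3, 50, 2))
  w <- init_resp_block(C_in = 3, F = 8, kernel_blk = 2, seed = 4)
  # zero weights and biases -> only the shortcut survives
  w0 <- rapply(w, function(a) a * 0, how = "replace")
  out <- resp_block(x, w0, d_blk = 3)
  m <- colMeans(x, dims = 1)
  expect_equal(out, array(rep(m, each = 8), dim = c(8, 50, 2)),
               tolerance = 1e-12)
  # zero input with zero biases -> exactly zero
  out0 <- resp_block(array(0, dim = c(3, 50, 2)), w0, d_blk = 3)
  expect_true(all(out0 == 0))
  # length preserved for both short and pipeline-length inputs
  for (L in c(64, 1800)) {
    xl <- array(rnorm(2 * L), dim = c(2, L, 1))
    wl <- init_resp_block(2, 4, kernel_blk = 3, seed = 1)
    expect_equal(dim(resp_block(xl, wl, d_blk = 2)), c(4, L, 1))
  }
  expect_error(resp_block(x, init_resp_block(5, 8, seed = 1)),
               "shape error")
})

test_that("network construction rejects inputs too short to survive the
           downsampling stack", {
  err <- tryCatch(build_dilated_resnet(tiny_cfg(n_blk = 2, input_len = 10)),
                  error = identity)
  expect_match(conditionMessage(err), "minimum admissible length is \\d+")
  min_len <- as.integer(sub(".*minimum admissible length is (\\d+).*", "\\1",
                            conditionMessage(err)))
  expect_no_error(build_dilated_resnet(tiny_cfg(n_blk = 2,
                                                input_len = min_len)))
  expect_error(build_dilated_resnet(tiny_cfg(n_blk = 2,
                                             input_len = min_len - 1L)))
})

test_that("a zeroed single-block network predicts its output bias", {
  cfg <- tiny_cfg(n_blk = 1)
  est <- build_dilated_resnet(cfg, seed = 1)
  theta <- ppgrr:::.flatten(est$params) * 0
  est$params <- ppgrr:::.unflatten(theta, est$params)
  est$params$head$dense2$b <- 7.5
  set.seed(2)
  x <- matrix(runif(4 * cfg$input_len), 4)
  expect_equal(predict(est, x), rep(7.5, 4), tolerance = 1e-6)
})

test_that("forward pass is pure and seeded training is deterministic", {
  cfg <- tiny_cfg()
  est <- build_dilated_resnet(cfg, seed = 3)
  est_b <- build_dilated_resnet(cfg, seed = 3)
  expect_identical(ppgrr:::.flatten(est$params),
                   ppgrr:::.flatten(est_b$params))
  set.seed(5)
  x <- matrix(runif(10 * cfg$input_len), 10)
  y <- runif(10, 6, 35)
  p1 <- predict(est, x)
  p2 <- predict(est, x)
  expect_identical(p1, p2)
  set.seed(11); r1 <- fit_epoch(est, x, y, 1e-3, 4L)
  set.seed(11); r2 <- fit_epoch(est_b, x, y, 1e-3, 4L)
  expect_identical(ppgrr:::.flatten(r1$est$params),
                   ppgrr:::.flatten(r2$est$params))
  expect_identical(r1$loss, r2$loss)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg(kernel_blk = 3L, d_blk = 2L, input_len = 60L)
  est <- build_dilated_resnet(cfg, seed = 2)
  set.seed(9)
  x <- matrix(runif(5 * cfg$input_len), 5)
  y <- runif(5, 10, 20)
  xb <- array(t(x), dim = c(1, cfg$input_len, 5))
  fw <- ppgrr:::.drn_forward(est$params, cfg, xb, keep_cache = TRUE)
  gr <- ppgrr:::.drn_backward(est$params, cfg, fw$cache,
                              sign(fw$out - y) / 5)
  flat_p <- ppgrr:::.flatten(est$params)
  flat_g <- ppgrr:::.flatten(gr)
  loss_at <- function(fp) {
    p <- ppgrr:::.unflatten(fp, est$params)
    mean(abs(ppgrr:::.drn_forward(p, cfg, xb)$out - y))
  }
  set.seed(13)
  idx <- sample(length(flat_p), 35)
  for (i in idx) {
    e <- 1e-6
    fp <- flat_p; fp[i] <- fp[i] + e; up <- loss_at(fp)
    fp[i] <- fp[i] - 2 * e; dn <- loss_at(fp)
    expect_equal((up - dn) / (2 * e), flat_g[i], tolerance = 1e-5)
  }
})

test_that("the fused float engine agrees with the reference path", {
  cfg <- tiny_cfg(n_blk = 3L, input_len = 300L)
  est <- build_dilated_resnet(cfg, seed = 4)
  set.seed(21)
  x <- matrix(runif(7 * cfg$input_len), 7)
  y <- runif(7, 6, 35)
  theta <- ppgrr:::.flatten(est$params)
  fused <- ppgrr:::.cpp_drn_fw_bw(theta, unclass(cfg), x, y)
  xb <- array(t(x), dim = c(1, cfg$input_len, 7))
  fw <- ppgrr:::.drn_forward(est$params, cfg, xb, keep_cache = TRUE)
  ref_g <- ppgrr:::.flatten(ppgrr:::.drn_backward(est$params, cfg, fw$cache,
                                                  sign(fw$out - y) / 7))
  expect_equal(fused$preds, unname(fw$out), tolerance = 1e-5)
  expect_equal(fused$loss, mean(abs(fw$out - y)), tolerance = 1e-5)
  expect_lt(max(abs(fused$grad - ref_g)), 1e-5 * max(1, max(abs(ref_g))))
})

test_that("every admissible hyperparameter-box corner builds and maps
           windows to scalars", {
  box <- ppgrr:::.drn_search_box()
  corners <- expand.grid(n_blk = box$n_blk, kernel_blk = box$kernel_blk,
                         d_blk = box$d_blk, kernel_dwn = box$kernel_dwn,
                         s_c = box$s_c)
  set.seed(8)
  x <- matrix(runif(2 * 1800), 2)
  for (i in seq_len(nrow(corners))) {
    cfg <- do.call(dilated_resnet_config,
                   c(as.list(corners[i, ]),
                     list(filters_c = 4L, n_den = 20L, input_len = 1800L)))
    built <- tryCatch(build_dilated_resnet(cfg, seed = 1), error = identity)
    if (inherits(built, "error")) {
      expect_match(conditionMessage(built), "minimum admissible length")
    } else {
      expect_length(predict(built, x), 2)
    }
  }
})

test_that("checkpoints round-trip the estimator", {
  cfg <- tiny_cfg()
  est <- build_dilated_resnet(cfg, seed = 6)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ck.rds")
  save_checkpoint(est, p)
  back <- load_checkpoint(p)
  set.seed(3)
  x <- matrix(runif(3 * cfg$input_len), 3)
  expect_identical(predict(back, x), predict(est, x))
  expect_error(load_checkpoint(file.path(dir, "missing.rds")), "not found")
})
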