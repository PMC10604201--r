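test_that("baseline summaries expose the stated layer widths", {
  lstm <- build_baseline("lstm", list(input_len = 256))
  df <- NULL
  capture.output(df <- summary(lstm))
  expect_equal(df$width[df$type == "recurrent"], 256)
  cnn <- build_baseline("cnn_lstm", list(input_len = 256))
  capture.output(df <- summary(cnn))
  expect_equal(df$width[df$type == "recurrent"], 256)
  bi <- build_baseline("bilstm", list(input_len = 256))
  capture.output(df <- summary(bi))
  expect_equal(df$width[df$type == "recurrent"], c(128, 128))
  expect_equal(sum(grepl("forward|backward", df$layer)), 2)
  at <- build_baseline("attn_bilstm", list(input_len = 256))
  capture.output(df <- summary(at))
  expect_equal(df$width[df$type == "recurrent"], c(64, 64))
  expect_true(any(df$type == "attention"))
  un <- build_baseline("unet_regressor", list(input_len = 256))
  capture.output(df <- summary(un))
  # encoder-decoder with a scalar dense head
  expect_equal(tail(df$width, 1), 1)
  expect_match(tail(df$layer, 1), "dense")
  expect_error(build_baseline("transformer"), "unknown baseline.*choices")
})

test_that("baselines honor the estimator contract: deterministic predict,
           aligned output length, trainable head", {
  set.seed(3)
  x <- matrix(runif(10 * 256), 10)
  y <- runif(10, 8, 30)
  ws <- ppgrr:::.window_set(x, data.frame(
    subject_id = rep(c("a", "b"), each = 5), window_index = 0, start_s = 0,
    rr_true = y, group = assign_group(y), stringsAsFactors = FALSE))
  for (nm in c("resnet", "lstm", "cnn_lstm", "bilstm", "attn_bilstm",
               "unet_regressor")) {
    est <- build_baseline(nm, list(input_len = 256))
    p1 <- predict(est, x)
    expect_length(p1, nrow(x))
    expect_identical(p1, predict(est, x))
    fitres <- fit_epoch(est, x, y, lr = 0, batch_size = 4)
    expect_lt(fitres$loss, mae(y, p1) + 1e-9)
    expect_false(identical(predict(fitres$est, x), p1))
  }
})

test_that("baselines plug into the training loop through the fit hook", {
  set.seed(5)
  x <- matrix(runif(12 * 128), 12)
  y <- runif(12, 10, 25)
  ws <- ppgrr:::.window_set(x, data.frame(
    subject_id = rep(c("a", "b", "c"), each = 4), window_index = 0,
    start_s = 0, rr_true = y, group = assign_group(y),
    stringsAsFactors = FALSE))
  tr <- subset_windows(ws, ws$meta$subject_id != "c")
  va <- subset_windows(ws, ws$meta$subject_id == "c")
  fit <- train_estimator(build_baseline("resnet", list(input_len = 128)),
                         tr, va,
                         train_config(max_epochs = 3,
                                      early_stop_patience = 2, seed = 1))
  expect_true(fit$estimator$trained)
  expect_true(is.finite(fit$best_val_mae))
})

test_that("hyperparameter search respects the box, the budget, and
           failure handling", {
  target <- c(n_blk = 4, kernel_blk = 2, d_blk = 3, kernel_dwn = 3,
              filters_c = 8, s_c = 2, n_den = 86)
  distance <- function(cfg) {
    sum(abs(unlist(cfg[names(target)]) - target))
  }
  # budget 1 returns the single evaluated config
  one <- bayes_search(distance, budget = 1, seed = 2, backend = "random")
  expect_s3_class(one, "dilated_resnet_config")
  expect_equal(nrow(attr(one, "evaluations")), 1)
  # proposals always lie inside the declared ranges
  box <- ppgrr:::.drn_search_box()
  ev <- attr(bayes_search(distance, budget = 40, seed = 3,
                          backend = "random"), "evaluations")
  for (nm in names(box)) {
    expect_true(all(ev[[nm]] >= box[[nm]][1] & ev[[nm]] <= box[[nm]][2]))
  }
  # the model-based backend recovers the optimum of a separable objective
  best <- bayes_search(distance, budget = 200, seed = 4, backend = "smbo")
  expect_equal(unlist(best[names(target)]), target, ignore_attr = TRUE)
  # random search returns the best config among those it evaluated
  evr <- attr(bayes_search(distance, budget = 30, seed = 5,
                           backend = "random"), "evaluations")
  expect_equal(min(evr$score),
               distance(bayes_search(distance, budget = 30, seed = 5,
                                     backend = "random")))
  # failing objective is scored +Inf with a warning; search continues
  flaky <- function(cfg) if (cfg$n_blk >= 3) stop("boom") else distance(cfg)
  warns <- capture_warnings(res <- bayes_search(flaky, budget = 25, seed = 6,
                                                backend = "random"))
  expect_true(any(grepl("objective failed", warns)))
  expect_lt(res$n_blk, 3)
})
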