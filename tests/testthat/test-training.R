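test_that("subject folds are a true partition with near-equal sizes", {
  ids <- sprintf("P%02d", 1:43)
  folds <- make_subject_folds(ids, k = 5, seed = 3)
  sizes <- sort(vapply(folds, function(f) length(f$val_ids), integer(1)))
  expect_equal(sizes, c(8L, 8L, 9L, 9L, 9L))
  all_val <- unlist(lapply(folds, `[[`, "val_ids"))
  expect_setequal(all_val, ids)
  expect_equal(length(all_val), length(ids))  # exactly once
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$val_ids), 0)
    expect_setequal(c(f$train_ids, f$val_ids), ids)
  }
  expect_identical(make_subject_folds(ids, 5, seed = 3), folds)
  expect_false(identical(make_subject_folds(ids, 5, seed = 4), folds))
  expect_error(make_subject_folds(ids[1:3], 5), "split error")
})

test_that("per-group test withdrawal draws the requested subject counts", {
  set.seed(2)
  rrs <- c(runif(2, 6, 11), runif(10, 12, 20), runif(5, 21, 34))
  records <- lapply(seq_along(rrs), function(i)
    const_rr_record(sprintf("S%02d", i), rrs[i]))
  sp <- split_test_by_group(records, c(slow = 1, normal = 3, rapid = 3),
                            seed = 1)
  expect_length(sp$test, 7)
  expect_length(sp$train, 10)
  test_groups <- vapply(sp$test, function(r)
    assign_group(rr_label_for_interval(r, 0, r$duration_s)), character(1))
  expect_equal(as.numeric(table(test_groups)[c("slow", "normal", "rapid")]),
               c(1, 3, 3))
  # empty request keeps everything in training
  sp0 <- split_test_by_group(records, c(slow = 0, normal = 0, rapid = 0))
  expect_length(sp0$test, 0)
  expect_length(sp0$train, length(records))
  # requesting more than available names the group
  expect_error(split_test_by_group(records, c(rapid = 9)), "'rapid'")
})

test_that("subject leakage between train and validation is a hard error", {
  ws <- two_subject_windows(c("A", "B", "C"))
  tr <- subset_windows(ws, ws$meta$subject_id %in% c("A", "B"))
  va <- subset_windows(ws, ws$meta$subject_id %in% c("B", "C"))
  expect_error(train_estimator(make_stub(1), tr, va, train_config()),
               "protocol violation.*B")
})

test_that("early stopping halts a frozen-loss run at patience + 1 epochs
           and the lr changes only by exact x0.1 steps", {
  ws <- two_subject_windows()
  tr <- subset_windows(ws, ws$meta$subject_id == "A")
  va <- subset_windows(ws, ws$meta$subject_id == "B")
  stub <- make_stub(losses = rep(2, 100))  # frozen validation loss
  cfg <- train_config(max_epochs = 100, plateau_patience = 4,
                      early_stop_patience = 12, seed = 1)
  fit <- train_estimator(stub, tr, va, cfg)
  # epoch 1 is the first (and only) improvement over Inf
  expect_equal(nrow(fit$history), 1 + cfg$early_stop_patience)
  expect_equal(fit$best_epoch, 1)
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  changes <- lr[-1] / head(lr, -1)
  expect_true(all(abs(changes - 1) < 1e-12 | abs(changes - 0.1) < 1e-12))
  # a decay fires each time plateau_patience epochs pass without
  # improvement; the early stop pre-empts the final one
  expect_equal(sum(abs(changes - 0.1) < 1e-12),
               floor((cfg$early_stop_patience - 1) / cfg$plateau_patience))
})

test_that("the best-validation checkpoint is returned, not the last", {
  ws <- two_subject_windows()
  tr <- subset_windows(ws, ws$meta$subject_id == "A")
  va <- subset_windows(ws, ws$meta$subject_id == "B")
  # loss improves until epoch 3 then worsens; patience exhausts
  stub <- make_stub(losses = c(3, 1, 0.5, 2, 2.5, rep(3, 50)))
  cfg <- train_config(max_epochs = 30, plateau_patience = 3,
                      early_stop_patience = 6, seed = 1)
  fit <- train_estimator(stub, tr, va, cfg)
  expect_equal(fit$best_epoch, 3)
  expect_equal(fit$best_val_mae, 0.5)
  expect_equal(nrow(fit$history), 3 + cfg$early_stop_patience)
  # returned estimator's validation MAE equals the best, and is no worse
  # than the final epoch's
  expect_lte(fit$best_val_mae, tail(fit$history$val_loss, 1))
  expect_equal(min(fit$history$val_loss), fit$best_val_mae)
})

test_that("seeded training histories are reproducible", {
  ws <- two_subject_windows()
  tr <- subset_windows(ws, ws$meta$subject_id == "A")
  va <- subset_windows(ws, ws$meta$subject_id == "B")
  cfg <- train_config(max_epochs = 8, early_stop_patience = 50, seed = 7)
  f1 <- train_estimator(make_stub(seq(2, 0.1, length.out = 60)), tr, va, cfg)
  f2 <- train_estimator(make_stub(seq(2, 0.1, length.out = 60)), tr, va, cfg)
  expect_identical(f1$history, f2$history)
})

test_that("cross-validation trains one estimator per fold without leakage", {
  ws <- two_subject_windows(ids = sprintf("S%d", 1:6))
  cv <- cross_validate(function() make_stub(rep(1, 50)), ws, k = 3,
                       cfg = train_config(max_epochs = 3,
                                          early_stop_patience = 2, seed = 1),
                       seed = 2)
  expect_length(cv$fold_maes, 3)
  expect_length(cv$estimators, 3)
  all_val <- unlist(lapply(cv$folds, `[[`, "val_ids"))
  expect_setequal(all_val, sprintf("S%d", 1:6))
})

test_that("a real network fit epoch reports MAE-on-brpm loss and updates
           weights", {
  cfg <- dilated_resnet_config(n_blk = 1, filters_c = 4, n_den = 20,
                               input_len = 90)
  est <- build_dilated_resnet(cfg, seed = 1)
  set.seed(2)
  x <- matrix(runif(12 * 90), 12)
  y <- runif(12, 10, 25)
  before <- predict(est, x)
  set.seed(1)
  r <- fit_epoch(est, x, y, lr = 1e-3, batch_size = 6L)
  expect_true(is.finite(r$loss) && r$loss > 0)
  # the reported loss is on the brpm scale of the targets
  expect_lt(abs(r$loss - mean(abs(before - y))), mean(abs(before - y)))
  expect_false(identical(ppgrr:::.flatten(r$est$params),
                         ppgrr:::.flatten(est$params)))
})
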