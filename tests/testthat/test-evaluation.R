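test_that("MAE matches its definition, a brute-force oracle, and is
           translation invariant", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(12, 20), c(14, 18)), 2)
  set.seed(1)
  a <- runif(1000, 5, 40); b <- runif(1000, 5, 40)
  brute <- 0
  for (i in seq_along(a)) brute <- brute + abs(a[i] - b[i])
  expect_equal(mae(a, b), brute / 1000, tolerance = 1e-12)
  expect_equal(mae(a + 3.7, b + 3.7), mae(a, b), tolerance = 1e-12)
  expect_error(mae(1:3, 1:4), "shape error")
})

test_that("fold MAE aggregation returns mean and sample SD", {
  expect_equal(mae_sd(rep(1, 5))[c("mean", "sd")], list(mean = 1, sd = 0))
  r <- mae_sd(c(1, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$sd, sqrt(2))
  one <- mae_sd(2.5)
  expect_true(one$single_fold)
  expect_equal(one$sd, 0)
  set.seed(2)
  v <- runif(5)
  m <- sum(v) / 5
  expect_equal(mae_sd(v)$sd, sqrt(sum((v - m)^2) / 4), tolerance = 1e-12)
})

fake_windows <- function(rr_true) {
  ppgrr:::.window_set(matrix(0, length(rr_true), 4),
                      data.frame(subject_id = "s", window_index = 0,
                                 start_s = 0, rr_true = rr_true,
                                 group = assign_group(rr_true),
                                 stringsAsFactors = FALSE))
}

test_that("stratified report on perfect and offset estimates", {
  set.seed(4)
  rr <- c(runif(20, 6, 11), runif(30, 12, 20), runif(10, 21, 34))
  w <- fake_windows(rr)
  perfect <- stratified_report(w, rr)
  expect_equal(report_mae(perfect, "all"), 0)
  expect_equal(report_mae(perfect, "slow"), 0)
  expect_equal(unname(perfect$bland_altman), c(0, 0, 0))
  expect_equal(perfect$pearson$r, 1)
  shifted <- stratified_report(w, rr + 1)
  expect_equal(report_mae(shifted, "all"), 1)
  expect_equal(unname(shifted$bland_altman["bias"]), 1)
  expect_equal(unname(shifted$bland_altman["loa_lower"]), 1)
  expect_equal(unname(shifted$bland_altman["loa_upper"]), 1)
  # perfectly linear positive relation -> r == 1
  lin <- stratified_report(w, 2 * rr + 3)
  expect_equal(lin$pearson$r, 1, tolerance = 1e-12)
  expect_true(lin$pearson$r >= -1 && lin$pearson$r <= 1)
  # constant estimates flag the undefined correlation
  const <- stratified_report(w, rep(15, length(rr)))
  expect_true(const$pearson$constant_input)
})

test_that("five-number summary and 1.5*IQR outliers match the hand case", {
  rr <- rep(10, 5)
  est <- rr + c(0, 1, 2, 3, 100)   # absolute errors 0,1,2,3,100
  rep5 <- stratified_report(fake_windows(rr), est)
  expect_equal(unname(rep5$fivenum), c(0, 1, 2, 3, 100))
  # upper fence = 3 + 1.5 * (3 - 1) = 6 -> exactly one outlier
  expect_equal(unname(rep5$outliers["count"]), 1)
  expect_equal(unname(rep5$outliers["fraction"]), 0.2)
  expect_lte(rep5$outliers["count"], rep5$n)
})

test_that("group Ns partition the total and group MAEs aggregate by
           window-count weighting", {
  set.seed(6)
  rr <- c(runif(15, 6, 11), runif(25, 12, 20), runif(12, 21, 34))
  est <- rr + rnorm(length(rr))
  rep_ <- stratified_report(fake_windows(rr), est)
  pg <- rep_$per_group
  n_groups <- pg$n[pg$group != "all"]
  expect_equal(sum(n_groups), pg$n[pg$group == "all"])
  weighted <- sum(pg$mae[pg$group != "all"] * n_groups) / sum(n_groups)
  expect_equal(weighted, pg$mae[pg$group == "all"], tolerance = 1e-9)
  # Bland-Altman bias equals the mean-difference oracle
  expect_equal(unname(rep_$bland_altman["bias"]), mean(est - rr),
               tolerance = 1e-12)
})

test_that("an absent breathing group is reported as absent, not zero", {
  rr <- runif(10, 13, 19)  # all normal
  rep_ <- stratified_report(fake_windows(rr), rr + 0.5)
  expect_true(is.na(report_mae(rep_, "slow")))
  expect_true(is.na(report_mae(rep_, "rapid")))
  expect_equal(report_mae(rep_, "normal"), 0.5)
})

test_that("SNR robustness tables are consistent with the clean pipeline
           and degrade under in-band artifacts", {
  est <- spectral_estimator()
  records <- list(quick_record(duration_s = 70, rr = 10, seed = 1, id = "r1"),
                  quick_record(duration_s = 70, rr = 16, seed = 2, id = "r2"),
                  quick_record(duration_s = 70, rr = 23, seed = 3, id = "r3"))
  tab <- snr_robustness(est, records, snr_levels = c(Inf, 20, 10), seed = 5)
  expect_equal(tab$level, c("Original", "Inf db", "20 db", "10 db"))
  # the Original row equals the stratified report on clean data
  ws <- preprocess_records(records)
  clean <- stratified_report(ws, predict(est, ws))
  expect_equal(tab$mae[1], report_mae(clean, "all"), tolerance = 1e-12)
  # injecting at +Inf dB reproduces the Original row exactly
  expect_equal(tab$mae[2], tab$mae[1], tolerance = 1e-12)
  expect_equal(tab$n, rep(n_windows(ws), 4))
  # strong in-band artifacts cannot improve the spectral estimator
  expect_gte(tab$mae[4], tab$mae[1] - 1e-9)
})

test_that("report tables serialize to CSV and Markdown", {
  dir <- withr::local_tempdir()
  df <- data.frame(model = c("a", "b"), mae = c(1.5, 2.25))
  write_report_table(df, file.path(dir, "t.csv"), file.path(dir, "t.md"))
  back <- read.csv(file.path(dir, "t.csv"))
  expect_equal(back$mae, df$mae)
  md <- readLines(file.path(dir, "t.md"))
  expect_match(md[1], "\\| model \\| mae \\|")
  expect_length(md, 4)
})
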