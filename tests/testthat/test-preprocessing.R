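test_that("band-pass design honors the response contract", {
  b <- design_bandpass(filter_spec(), fs = 125)
  expect_length(as.numeric(b), filter_spec()$taps)
  g25 <- filter_gain_db(b, 0.25)
  expect_gte(g25, -3)
  expect_lte(g25, 0.1)
  expect_lte(filter_gain_db(b, 1.0), -20)
  expect_lte(filter_gain_db(b, 2.0), -20)
  # symmetric taps -> linear phase
  bb <- as.numeric(b)
  expect_equal(bb, rev(bb))
  expect_error(filter_spec(low_hz = 0.5, high_hz = 0.4), "low_hz < high_hz")
  expect_error(filter_spec(taps = 1024), "odd")
  # far too short a filter cannot meet the attenuation contract
  expect_error(design_bandpass(filter_spec(taps = 101), 125),
               "increase `taps`")
})

test_that("zero-phase filtering preserves the respiratory band and
           attenuates the cardiac band", {
  fs <- 125
  t <- (0:(90 * fs - 1)) / fs
  b <- design_bandpass(filter_spec(), fs)
  core <- (20 * fs):(70 * fs)  # interior, away from edge transients
  resp <- apply_filter(sin(2 * pi * 0.25 * t), b)
  expect_gt(fitted_amplitude(resp[core], 0.25, fs), 0.9)
  card <- apply_filter(sin(2 * pi * 1.5 * t), b)
  expect_lt(fitted_amplitude(card[core], 1.5, fs), 0.1)
  expect_equal(apply_filter(numeric(20 * fs), b), numeric(20 * fs))
  expect_error(apply_filter(numeric(100), b), "length error")
})

test_that("linear resampling has exact length and reproduces lines", {
  x <- rnorm(7500)
  y <- resample_linear(x, 125, 30)
  expect_length(y, 1800)
  expect_identical(resample_linear(x, 125, 125), x)
  ramp <- seq(0, 1, length.out = 1250)
  r30 <- resample_linear(ramp, 125, 30)
  t_out <- (seq_along(r30) - 1) / 30
  expect_equal(r30, t_out / (1249 / 125), tolerance = 1e-12)
  expect_error(resample_linear(x, 125, 0), "positive")
  expect_error(resample_linear(x, 125, 250), "exceed")
})

test_that("min-max normalization maps windows onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  ramp <- seq(0, 1, length.out = 11)
  expect_equal(minmax_normalize(ramp), ramp)
  const <- minmax_normalize(c(5, 5, 5))
  expect_equal(as.numeric(const), rep(0.5, 3))
  expect_true(attr(const, "constant"))
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("breathing groups use inclusive 12-20 boundaries", {
  expect_equal(assign_group(11.9), "slow")
  expect_equal(assign_group(12), "normal")
  expect_equal(assign_group(20), "normal")
  expect_equal(assign_group(20.1), "rapid")
  expect_equal(assign_group(c(0, 35)), c("slow", "rapid"))
  expect_error(assign_group(-1), "non-negative")
})

test_that("an 8-minute record slices into 421 labeled windows", {
  rec <- quick_record(duration_s = 480, rr = 14, seed = 11, id = "w1")
  ws <- slice_windows(rec)
  expect_equal(n_windows(ws), 421)  # floor((480-60)/1) + 1
  expect_equal(ncol(ws$x), 1800)
  expect_true(all(ws$x >= 0 & ws$x <= 1))
  expect_true(all(ws$meta$rr_true == 14))
  expect_true(all(ws$meta$group == assign_group(ws$meta$rr_true)))
  expect_equal(ws$meta$start_s, 0:420)
})

test_that("window counts match brute-force enumeration for any
           duration/shift", {
  for (dur in c(60, 61, 75, 124)) {
    for (shift in c(1, 2, 5)) {
      rec <- quick_record(duration_s = dur, seed = dur + shift, id = "x")
      ws <- slice_windows(rec, window_spec(length_s = 60, shift_s = shift))
      brute <- sum(seq(0, dur, by = shift) + 60 <= dur + 1e-9)
      expect_equal(n_windows(ws), floor((dur - 60) / shift) + 1)
      expect_equal(n_windows(ws), brute)
    }
  }
})

test_that("the pipeline is deterministic and matches its per-window
           decomposition", {
  rec <- quick_record(duration_s = 80, rr = 13, seed = 2, id = "det")
  ws1 <- slice_windows(rec)
  ws2 <- slice_windows(rec)
  expect_identical(ws1$x, ws2$x)
  expect_identical(ws1$meta, ws2$meta)
  # window 5 equals filter -> slice -> resample -> normalize done by hand
  b <- design_bandpass(filter_spec(), rec$fs)
  filtered <- apply_filter(rec$ppg, b)
  seg <- filtered[(5 * 125 + 1):(5 * 125 + 7500)]
  manual <- minmax_normalize(resample_linear(seg, 125, 30))
  expect_equal(ws1$x[6, ], as.numeric(manual), tolerance = 1e-12)
})

test_that("records shorter than one window emit an empty set with a
           warning", {
  rec <- const_rr_record("tiny", 15, duration_s = 30, fs = 125)
  expect_warning(ws <- slice_windows(rec), "shorter than one window")
  expect_equal(n_windows(ws), 0)
})

test_that("window sets persist as flat binary plus manifest and combine", {
  recs <- list(quick_record(duration_s = 65, rr = 10, seed = 1, id = "a"),
               quick_record(duration_s = 65, rr = 22, seed = 2, id = "b"))
  ws <- preprocess_records(recs)
  expect_equal(n_windows(ws), 12)
  expect_setequal(unique(ws$meta$group), c("slow", "rapid"))
  dir <- withr::local_tempdir()
  write_window_set(ws, dir)
  back <- read_window_set(dir)
  expect_equal(back$x, ws$x)
  expect_equal(back$meta, ws$meta, ignore_attr = TRUE)
  expect_error(read_window_set(file.path(dir, "nope")), "no window dataset")
  # subsetting keeps rows aligned
  sub <- subset_windows(ws, ws$meta$group == "rapid")
  expect_true(all(sub$meta$rr_true > 20))
  expect_equal(nrow(sub$x), nrow(sub$meta))
})
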