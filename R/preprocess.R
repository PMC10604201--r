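#' Band-pass filter specification
#'
#' Respiratory content of a PPG lives in a narrow low-frequency band; the
#' pipeline isolates it with a linear-phase FIR band-pass (Hamming window
#' design) with cut-offs 0.1-0.4 Hz. The tap count defaults to 1537: a
#' passband this close to DC needs a long impulse response before the
#' transition bands sharpen enough to keep 0.15-0.35 Hz within -3 dB
#' while rejecting the cardiac fundamental (~1-2 Hz). The normative requirement is the frequency-response contract
#' checked by [design_bandpass()], not the tap count itself.
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param taps Filter length (odd, so the filter has integer group delay).
#' @param window_name Design window; only `"hamming"` is supported.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 0.4, taps = 1537L,
                        window_name = "hamming") {
  taps <- as.integer(taps)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("design error: require 0 < low_hz < high_hz", call. = FALSE)
  }
  if (taps < 3L || taps %% 2L == 0L) {
    stop("design error: `taps` must be an odd integer >= 3", call. = FALSE)
  }
  if (!identical(window_name, "hamming")) {
    stop("only the Hamming design window is supported", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, taps = taps,
                 window_name = window_name), class = "filter_spec")
}

#' Windowing specification
#'
#' Sixty-second windows with a one-second shift (RR is conventionally
#' counted per minute), resampled to 30 Hz, give fixed-length inputs of
#' `length_s * target_fs` samples (1800 at defaults).
#'
#' @param length_s Window length in seconds.
#' @param shift_s Shift between consecutive windows in seconds.
#' @param target_fs Post-resampling rate in Hz.
#' @return A `window_spec` object.
#' @export
window_spec <- function(length_s = 60, shift_s = 1, target_fs = 30) {
  if (shift_s <= 0 || shift_s > length_s) {
    stop("require 0 < shift_s <= length_s", call. = FALSE)
  }
  if (target_fs <= 0) stop("target_fs must be positive", call. = FALSE)
  structure(list(length_s = length_s, shift_s = shift_s,
                 target_fs = target_fs), class = "window_spec")
}

#' Design the respiratory band-pass FIR filter
#'
#' Designs a linear-phase Hamming-window FIR band-pass for sampling rate
#' `fs` and verifies the response contract by direct transfer-function
#' evaluation: gain within -3 dB of unity across 0.15-0.35 Hz and at or
#' below -20 dB everywhere at and above 1 Hz. A design that cannot meet
#' the contract (too few taps) is an error suggesting a longer filter.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate of the signal to be filtered, in Hz.
#' @return Numeric coefficient vector of length `spec$taps` with attributes
#'   `fs` and `spec`.
#' @export
design_bandpass <- function(spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_hz >= fs / 2) {
    stop("design error: high_hz must be below the Nyquist rate", call. = FALSE)
  }
  b <- signal::fir1(spec$taps - 1L,
                    c(spec$low_hz, spec$high_hz) / (fs / 2),
                    type = "pass",
                    window = signal::hamming(spec$taps))
  b <- as.numeric(b)
  pass_f <- seq(0.15, 0.35, by = 0.025)
  stop_f <- unique(pmin(c(1, 1.5, 2, 5, 10, 20, fs / 2 * 0.98), fs / 2 * 0.999))
  stop_f <- stop_f[stop_f >= 1]
  gain_db <- function(f) 20 * log10(abs(.fir_response(b, f, fs)))
  if (any(gain_db(pass_f) < -3) || any(gain_db(stop_f) > -20)) {
    stop(sprintf(paste0(
      "design error: %d taps cannot meet the band-pass contract at fs = %g Hz; ",
      "increase `taps` (try %d)"), spec$taps, fs, 2L * spec$taps + 1L),
      call. = FALSE)
  }
  structure(b, fs = fs, spec = spec)
}

# complex frequency response of an FIR at frequencies f (Hz)
.fir_response <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(fi) sum(b * exp(-2i * pi * fi * k / fs)),
         complex(1))
}

#' Evaluate FIR filter gain in dB
#'
#' @param coeffs FIR coefficients (as from [design_bandpass()]).
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz (defaults to the design rate attached to
#'   `coeffs`).
#' @return Gain in dB at each frequency.
#' @export
filter_gain_db <- function(coeffs, f, fs = attr(coeffs, "fs")) {
  20 * log10(abs(.fir_response(as.numeric(coeffs), f, fs)))
}

#' Apply the band-pass filter (zero-phase)
#'
#' Forward-backward application, so the filtered waveform has no group
#' delay and window labels stay aligned with the breathing they describe.
#'
#' @param ppg Numeric sample vector, longer than the filter.
#' @param coeffs FIR coefficients.
#' @return Filtered vector, same length as the input.
#' @export
apply_filter <- function(ppg, coeffs) {
  if (length(ppg) <= length(coeffs)) {
    stop("length error: input must be longer than the filter", call. = FALSE)
  }
  x <- as.numeric(ppg)
  b <- as.numeric(coeffs)
  # forward-backward FIR filtering is linear convolution with the
  # filter's autocorrelation (zero-phase, centered); done by FFT for
  # speed and identical (to rounding) to filtering twice with reversal
  n <- length(x)
  L <- length(b)
  m <- stats::nextn(n + 2L * (L - 1L))
  H <- stats::fft(c(b, numeric(m - L)))
  acf_b <- Re(stats::fft(H * Conj(H), inverse = TRUE)) / m  # circular acf
  # recover linear autocorrelation (length 2L-1, centered at L)
  h2 <- c(acf_b[(m - L + 2L):m], acf_b[1:L])
  y_full <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                            stats::fft(c(h2, numeric(m - 2L * L + 1L))),
                          inverse = TRUE)) / m
  y_full[L:(L + n - 1L)]
}

#' Linear-interpolation resampling
#'
#' @param x Sample vector at rate `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates in Hz
#'   (`fs_out <= fs_in`).
#' @return Vector of length `round(length(x) * fs_out / fs_in)` obtained by
#'   linear interpolation on the uniform output time grid.
#' @export
resample_linear <- function(x, fs_in, fs_out) {
  if (!is.numeric(fs_out) || fs_out <= 0) {
    stop("parameter error: fs_out must be positive", call. = FALSE)
  }
  if (fs_out > fs_in) {
    stop("parameter error: fs_out must not exceed fs_in", call. = FALSE)
  }
  if (fs_out == fs_in) return(as.numeric(x))
  n_out <- round(length(x) * fs_out / fs_in)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  approx(t_in, as.numeric(x), xout = t_out, rule = 2)$y
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a window so its minimum maps to 0 and maximum to 1. A constant
#' window has no scale; it is returned as all 0.5 with attribute
#' `constant = TRUE` so callers can flag or drop it.
#'
#' @param values Non-empty numeric vector.
#' @return Normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  values <- as.numeric(values)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(rep(0.5, length(values)), constant = TRUE))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Breathing-group assignment
#'
#' Strata used for evaluation: slow below 12 brpm, normal 12 to 20 brpm
#' (both endpoints included), rapid above 20 brpm.
#'
#' @param rr RR value(s) in breaths per minute (non-negative).
#' @return Character vector over `{"slow", "normal", "rapid"}`.
#' @export
assign_group <- function(rr) {
  rr <- as.numeric(rr)
  if (any(rr < 0, na.rm = TRUE)) {
    stop("parameter error: rr must be non-negative", call. = FALSE)
  }
  ifelse(rr < 12, "slow", ifelse(rr <= 20, "normal", "rapid"))
}

#' Slice a record into preprocessed, labeled window samples
#'
#' Runs the preprocessing chain in recording order: band-pass filter the
#' whole record once at its native rate, slice 60 s windows every
#' `shift_s` seconds, linearly resample each window to `target_fs`,
#' min-max normalize per window, and label each window with
#' [rr_label_for_interval()] and [assign_group()]. Windows are half-open
#' `[start, start + length_s)` intervals.
#'
#' The number of windows is exactly
#' `floor((duration_s - length_s) / shift_s) + 1`.
#'
#' @param record A [ppg_record()].
#' @param wspec A [window_spec()].
#' @param fspec A [filter_spec()].
#' @param label_stat Passed to [rr_label_for_interval()] for RR-series
#'   references.
#' @return A `window_set`: list with matrix `x` (windows in rows) and
#'   data.frame `meta` (`subject_id`, `window_index`, `start_s`, `rr_true`,
#'   `group`).
#' @export
slice_windows <- function(record, wspec = window_spec(),
                          fspec = filter_spec(), label_stat = "mean") {
  stopifnot(inherits(record, "ppg_record"), inherits(wspec, "window_spec"),
            inherits(fspec, "filter_spec"))
  n_per_win <- round(wspec$length_s * wspec$target_fs)
  if (record$duration_s < wspec$length_s) {
    warning(sprintf("record %s shorter than one window; no windows emitted",
                    record$subject_id), call. = FALSE)
    return(.window_set(matrix(numeric(0), 0, n_per_win),
                       .empty_window_meta()))
  }
  coeffs <- design_bandpass(fspec, record$fs)
  filtered <- apply_filter(record$ppg, coeffs)
  starts <- seq(0, record$duration_s - wspec$length_s, by = wspec$shift_s)
  n_raw <- round(wspec$length_s * record$fs)
  x <- matrix(0, length(starts), n_per_win)
  rr_true <- numeric(length(starts))
  for (i in seq_along(starts)) {
    i0 <- round(starts[i] * record$fs)
    seg <- filtered[(i0 + 1L):(i0 + n_raw)]
    seg <- resample_linear(seg, record$fs, wspec$target_fs)
    x[i, ] <- minmax_normalize(seg)
    rr_true[i] <- rr_label_for_interval(record, starts[i],
                                        starts[i] + wspec$length_s,
                                        stat = label_stat)
  }
  meta <- data.frame(
    subject_id = record$subject_id,
    window_index = seq_along(starts) - 1L,
    start_s = starts,
    rr_true = rr_true,
    group = assign_group(rr_true),
    stringsAsFactors = FALSE
  )
  .window_set(x, meta)
}

.empty_window_meta <- function() {
  data.frame(subject_id = character(0), window_index = integer(0),
             start_s = numeric(0), rr_true = numeric(0),
             group = character(0), stringsAsFactors = FALSE)
}

.window_set <- function(x, meta) {
  structure(list(x = x, meta = meta), class = "window_set")
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) nrow(ws$x)

#' Combine window sets
#' @param ... `window_set` objects (or one list of them).
#' @return A single combined `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "window_set")) {
    sets <- sets[[1L]]
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "window_set")))
  .window_set(do.call(rbind, lapply(sets, `[[`, "x")),
              do.call(rbind, lapply(sets, `[[`, "meta")))
}

#' Subset a window set by row index or predicate on its metadata
#' @param ws A `window_set`.
#' @param i Integer/logical row index into the windows.
#' @return The subset `window_set`.
#' @export
subset_windows <- function(ws, i) {
  .window_set(ws$x[i, , drop = FALSE], ws$meta[i, , drop = FALSE])
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d samples, %d subject(s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$meta$subject_id))))
  if (nrow(x$x)) {
    cat(sprintf("  rr_true: %.1f-%.1f brpm; groups: %s\n",
                min(x$meta$rr_true), max(x$meta$rr_true),
                paste(names(table(x$meta$group)), table(x$meta$group),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Preprocess a list of records into one window set
#'
#' @param records List of [ppg_record()] objects.
#' @param wspec,fspec Window and filter specifications.
#' @param label_stat Passed to [slice_windows()].
#' @return A combined `window_set`.
#' @export
preprocess_records <- function(records, wspec = window_spec(),
                               fspec = filter_spec(), label_stat = "mean") {
  bind_windows(lapply(records, slice_windows, wspec = wspec,
                      fspec = fspec, label_stat = label_stat))
}

#' Persist a window set as flat binary values plus a CSV manifest
#'
#' Stores the window matrix row-major as IEEE doubles in `values.bin` and
#' the metadata as `manifest.csv`, so splits and experiments can be
#' reproduced from disk.
#'
#' @param ws A `window_set`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_window_set <- function(ws, dir) {
  stopifnot(inherits(ws, "window_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- file(file.path(dir, "values.bin"), "wb")
  writeBin(as.numeric(t(ws$x)), con, size = 8, endian = "little")
  close(con)
  meta <- ws$meta
  meta$n_samples <- ncol(ws$x)
  write.csv(meta, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a window set written by [write_window_set()]
#'
#' @param dir Directory containing `values.bin` and `manifest.csv`.
#' @return A `window_set`.
#' @export
read_window_set <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  values <- file.path(dir, "values.bin")
  if (!file.exists(manifest) || !file.exists(values)) {
    stop(sprintf("no window dataset found under %s", dir), call. = FALSE)
  }
  meta <- read.csv(manifest, stringsAsFactors = FALSE)
  p <- if (nrow(meta)) meta$n_samples[1L] else 0L
  con <- file(values, "rb")
  vals <- readBin(con, "double", n = nrow(meta) * p, size = 8,
                  endian = "little")
  close(con)
  meta$n_samples <- NULL
  .window_set(matrix(vals, nrow(meta), p, byrow = TRUE), meta)
}
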