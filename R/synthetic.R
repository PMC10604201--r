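# Respiratory-modulated synthetic PPG.
#
# The generator reproduces the three mechanisms by which breathing imprints
# itself on a PPG: additive baseline wander at the respiratory frequency,
# amplitude modulation of the cardiac pulses, and frequency modulation of
# the beat-to-beat interval (respiratory sinus arrhythmia). The cardiac
# pulse is a fixed two-Gaussian systolic/diastolic template placed at beat
# times derived from the modulated instantaneous heart rate; because the
# template has a fixed duration in seconds, rate modulation changes the
# local duty cycle and therefore also leaves a low-frequency trace at the
# respiratory frequency, as it does in real recordings.

#' Synthetic PPG configuration
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_bpm Cardiac rate in beats per minute.
#' @param rr_brpm Respiratory rate in breaths per minute
#'   (`hr_bpm > rr_brpm > 0`).
#' @param bw_depth Baseline-wander amplitude as a fraction of the unit
#'   systolic peak.
#' @param am_depth Amplitude-modulation depth in `[0, 1)`.
#' @param fm_depth Frequency-modulation depth in `[0, 1)` (fractional swing
#'   of the instantaneous heart rate).
#' @param noise_sd Additive white-noise standard deviation.
#' @param seed Optional RNG seed for the noise draw.
#' @return A `synth_config` object.
#' @export
synth_config <- function(duration_s = 480, fs = 125, hr_bpm = 75,
                         rr_brpm = 15, bw_depth = 0.2, am_depth = 0.15,
                         fm_depth = 0.1, noise_sd = 0.01, seed = NULL) {
  if (!(hr_bpm > rr_brpm && rr_brpm > 0)) {
    stop("parameter error: require hr_bpm > rr_brpm > 0", call. = FALSE)
  }
  if (bw_depth < 0 || noise_sd < 0) {
    stop("parameter error: depths and noise_sd must be non-negative",
         call. = FALSE)
  }
  if (am_depth < 0 || am_depth >= 1 || fm_depth < 0 || fm_depth >= 1) {
    stop("parameter error: am_depth and fm_depth must lie in [0, 1)",
         call. = FALSE)
  }
  if (fs < 4 * hr_bpm / 60) {
    stop("parameter error: fs too low for the cardiac harmonic bandwidth",
         call. = FALSE)
  }
  structure(list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
                 rr_brpm = rr_brpm, bw_depth = bw_depth,
                 am_depth = am_depth, fm_depth = fm_depth,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

# run expr with a fixed RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# two-Gaussian cardiac-cycle template, fixed in seconds
.pulse_template <- list(a = c(1.0, 0.45), mu = c(0.18, 0.42),
                        sigma = c(0.055, 0.10))

#' Generate a respiratory-modulated synthetic PPG record
#'
#' Builds
#' `ppg(t) = (1 + am * sin(2*pi*fr*t)) * pulses(t) + bw * sin(2*pi*fr*t) +
#' noise`, where `fr = rr_brpm / 60` and `pulses` is a train of fixed
#' two-Gaussian cardiac templates whose beat times follow the instantaneous
#' rate `hr_bpm/60 * (1 + fm * sin(2*pi*fr*t))`. The reference RR is a
#' constant 1 Hz [rr_series()] at `rr_brpm`.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Identifier for the generated record.
#' @return A [ppg_record()]; the true rates are kept under `meta`.
#' @export
generate_ppg <- function(cfg = synth_config(), subject_id = "synth") {
  stopifnot(inherits(cfg, "synth_config"))
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  fr <- cfg$rr_brpm / 60
  fc <- cfg$hr_bpm / 60

  # integrated instantaneous cardiac frequency -> cardiac phase
  phase <- fc * (t - cfg$fm_depth / (2 * pi * fr) * (cos(2 * pi * fr * t) - 1))
  k_max <- floor(phase[n])
  beats <- approx(phase, t, xout = seq(-2L, k_max + 2L), rule = 2)$y

  tmpl <- .pulse_template
  pulses <- numeric(n)
  span <- max(tmpl$mu + 4 * tmpl$sigma)
  for (tb in beats) {
    i0 <- max(1L, floor(tb * cfg$fs) + 1L)
    i1 <- min(n, ceiling((tb + span) * cfg$fs) + 1L)
    if (i0 > i1) next
    tau <- t[i0:i1] - tb
    pulses[i0:i1] <- pulses[i0:i1] +
      tmpl$a[1] * exp(-(tau - tmpl$mu[1])^2 / (2 * tmpl$sigma[1]^2)) +
      tmpl$a[2] * exp(-(tau - tmpl$mu[2])^2 / (2 * tmpl$sigma[2]^2))
  }

  resp <- sin(2 * pi * fr * t)
  ppg <- (1 + cfg$am_depth * resp) * pulses + cfg$bw_depth * resp
  if (cfg$noise_sd > 0) {
    ppg <- ppg + .with_seed(cfg$seed, rnorm(n, 0, cfg$noise_sd))
  }

  ref_t <- seq(0, cfg$duration_s - 1)
  ppg_record(
    subject_id = subject_id, ppg = ppg, fs = cfg$fs,
    duration_s = cfg$duration_s,
    rr_reference = rr_series(ref_t, rep(cfg$rr_brpm, length(ref_t))),
    meta = list(true_rr_brpm = cfg$rr_brpm, true_hr_bpm = cfg$hr_bpm,
                synth_config = cfg)
  )
}

#' SNR-calibrated artifact specification
#'
#' @param target_db Target signal-to-noise ratio in dB (`Inf` disables
#'   injection).
#' @param artifact_band_hz Frequency band the wander components are drawn
#'   from; the default 0.05-1 Hz spans motion/baseline wander overlapping
#'   the respiratory band.
#' @param n_components Number of random sinusoids composing the artifact.
#' @param seed RNG seed for the artifact draw.
#' @return An `snr_spec` object.
#' @export
snr_spec <- function(target_db, artifact_band_hz = c(0.05, 1.0),
                     n_components = 12L, seed = NULL) {
  if (!is.numeric(target_db) || length(target_db) != 1L || is.na(target_db)) {
    stop("parameter error: target_db must be a numeric scalar", call. = FALSE)
  }
  if (!(artifact_band_hz[1] < artifact_band_hz[2])) {
    stop("parameter error: artifact band must satisfy f_lo < f_hi",
         call. = FALSE)
  }
  structure(list(target_db = target_db,
                 artifact_band_hz = as.numeric(artifact_band_hz),
                 n_components = as.integer(n_components), seed = seed),
            class = "snr_spec")
}

#' Inject a baseline-wander artifact at a target SNR
#'
#' Adds a random multi-sinusoid wander (frequencies drawn uniformly in the
#' artifact band, random phases and relative amplitudes) scaled so that
#' `10*log10(P_signal / P_artifact)` equals `target_db`, with powers taken
#' as mean squared amplitude of the mean-removed sequences. A `target_db`
#' of `Inf` returns the record unchanged.
#'
#' @param record A clean [ppg_record()].
#' @param spec An [snr_spec()].
#' @return The record with the artifact added (`meta$snr_db` records the
#'   target).
#' @export
inject_artifact_to_snr <- function(record, spec) {
  stopifnot(inherits(record, "ppg_record"), inherits(spec, "snr_spec"))
  if (is.infinite(spec$target_db) && spec$target_db > 0) return(record)
  x <- record$ppg
  p_sig <- mean((x - mean(x))^2)
  if (p_sig == 0) {
    stop("SNR undefined for a zero-power input signal", call. = FALSE)
  }
  n <- length(x)
  t <- (seq_len(n) - 1) / record$fs
  art <- .with_seed(spec$seed, {
    f <- runif(spec$n_components, spec$artifact_band_hz[1],
               spec$artifact_band_hz[2])
    ph <- runif(spec$n_components, 0, 2 * pi)
    a <- runif(spec$n_components, 0.3, 1)
    colSums(a * sin(outer(2 * pi * f, t) + ph))
  })
  art <- art - mean(art)
  p_art <- mean(art^2)
  art <- art * sqrt(p_sig / (p_art * 10^(spec$target_db / 10)))
  out <- record
  out$ppg <- x + art
  out$meta$snr_db <- spec$target_db
  out
}

#' Measure signal-to-noise ratio between a clean and a noisy sequence
#'
#' `10*log10(P_clean / P_(noisy - clean))` with powers of the mean-removed
#' sequences. Identical inputs return `Inf`.
#'
#' @param clean,noisy Equal-length numeric vectors.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy) {
  if (length(clean) != length(noisy)) {
    stop("shape error: sequences must have equal length", call. = FALSE)
  }
  noise <- noisy - clean
  if (all(noise == 0)) return(Inf)
  p_c <- mean((clean - mean(clean))^2)
  p_n <- mean((noise - mean(noise))^2)
  10 * log10(p_c / p_n)
}

#' Dominant spectral frequency within a band
#'
#' Periodogram argmax restricted to `band`; the attribute `bin_hz` carries
#' the FFT bin width for tolerance bookkeeping.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band Two-element frequency band in Hz.
#' @return Frequency (Hz) of the largest periodogram ordinate in the band.
#' @export
dominant_frequency <- function(x, fs, band = c(0.1, 0.4)) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2L)]^2
  freqs <- (seq_len(n %/% 2L) - 1) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2]
  structure(freqs[keep][which.max(spec[keep])], bin_hz = fs / n)
}

#' Generate a cohort of synthetic subjects across breathing groups
#'
#' Subjects are allocated to breathing groups by `group_mix`; per-subject
#' rates are drawn uniformly within each group's RR range (slow 6-11.5,
#' normal 12-20, rapid 20.5-35 brpm) and heart rates uniformly in
#' 55-110 bpm. Deterministic under `seed`.
#'
#' @param n_subjects Number of subjects (positive).
#' @param group_mix Named proportions over `c(slow, normal, rapid)`,
#'   summing to one.
#' @param duration_s,fs Record length and sampling rate.
#' @param seed RNG seed.
#' @param ... Further [synth_config()] fields (modulation depths,
#'   noise_sd).
#' @return List of [ppg_record()]s with a `manifest` attribute
#'   (data.frame of subject_id, group, rr_brpm, hr_bpm).
#' @export
make_cohort <- function(n_subjects,
                        group_mix = c(slow = 1/3, normal = 1/3, rapid = 1/3),
                        duration_s = 480, fs = 125, seed = NULL, ...) {
  if (n_subjects <= 0) {
    stop("parameter error: n_subjects must be positive", call. = FALSE)
  }
  if (abs(sum(group_mix) - 1) > 1e-8) {
    stop("parameter error: group_mix must sum to 1", call. = FALSE)
  }
  groups <- c("slow", "normal", "rapid")
  mix <- group_mix[groups]
  mix[is.na(mix)] <- 0
  counts <- floor(mix * n_subjects)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    frac <- mix * n_subjects - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  rr_range <- list(slow = c(6, 11.5), normal = c(12, 20),
                   rapid = c(20.5, 35))
  .with_seed(seed, {
    subj_group <- sample(rep(groups, counts))
    rr <- vapply(subj_group, function(g)
      runif(1, rr_range[[g]][1], rr_range[[g]][2]), numeric(1))
    hr <- runif(n_subjects, 55, 110)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    ids <- sprintf("S%03d", seq_len(n_subjects))
    records <- lapply(seq_len(n_subjects), function(i) {
      cfg <- synth_config(duration_s = duration_s, fs = fs,
                          hr_bpm = hr[i], rr_brpm = rr[i],
                          seed = sub_seeds[i], ...)
      generate_ppg(cfg, subject_id = ids[i])
    })
    structure(records,
              manifest = data.frame(subject_id = ids, group = subj_group,
                                    rr_brpm = rr, hr_bpm = hr,
                                    stringsAsFactors = FALSE))
  })
}

#' Cohort manifest accessor
#' @param cohort A cohort from [make_cohort()].
#' @return The manifest data.frame (subject_id, group, rr_brpm, hr_bpm).
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")
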