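# Fixtures are generated in code at test time; nothing is read from disk
# except what the tests themselves write to tempdir().

# short synthetic record with a constant RR-series reference
quick_record <- function(duration_s = 70, rr = 15, hr = 75, seed = 1,
                         id = "S1", ...) {
  generate_ppg(synth_config(duration_s = duration_s, fs = 125, hr_bpm = hr,
                            rr_brpm = rr, seed = seed, ...),
               subject_id = id)
}

# minimal record with an arbitrary reference, cheap to build (flat PPG)
flat_record <- function(id, rr_reference, duration_s = 10, fs = 10) {
  n <- round(duration_s * fs)
  ppg_record(subject_id = id, ppg = sin(seq_len(n)), fs = fs,
             duration_s = duration_s, rr_reference = rr_reference)
}

const_rr_record <- function(id, rr, duration_s = 10, fs = 10) {
  t_ref <- seq(0, duration_s - 1)
  flat_record(id, rr_series(t_ref, rep(rr, length(t_ref))),
              duration_s = duration_s, fs = fs)
}

# least-squares amplitude of a sinusoid of known frequency in x
fitted_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, x - mean(x))
  sqrt(sum(cf^2))
}

# spectral stub estimator: periodogram argmax of each 30 Hz window, in
# brpm -- used where evaluation tests need a deterministic estimator
# without training a network
spectral_estimator <- function() {
  est <- structure(list(name = "spectral_stub", trained = TRUE),
                   class = c("spectral_stub", "ppgrr_estimator"))
  registerS3method("predict", "spectral_stub",
                   function(object, newdata, ...) {
                     x <- if (inherits(newdata, "window_set")) newdata$x else newdata
                     apply(x, 1L, function(w)
                       60 * as.numeric(dominant_frequency(w, 30, c(0.08, 0.62))))
                   },
                   envir = asNamespace("ppgrr"))
  est
}

# stub estimator with a scripted validation-loss trajectory, used to test
# the training loop contract without network cost
make_stub <- function(losses) {
  env <- new.env()
  env$epoch <- 0L
  registerS3method("fit_epoch", "loop_stub",
                   function(est, x, y, lr, batch_size = 256L) {
                     est$env$epoch <- est$env$epoch + 1L
                     est$env$lr_trace <- c(est$env$lr_trace, lr)
                     list(est = est, loss = 1)
                   }, envir = asNamespace("ppgrr"))
  registerS3method("predict", "loop_stub",
                   function(object, newdata, ...) {
                     n <- nrow(newdata$x)
                     off <- object$env$losses[min(object$env$epoch,
                                                  length(object$env$losses))]
                     newdata$meta$rr_true + off
                   }, envir = asNamespace("ppgrr"))
  env$losses <- losses
  structure(list(name = "loop_stub", env = env, trained = FALSE),
            class = c("loop_stub", "ppgrr_estimator"))
}

two_subject_windows <- function(ids = c("A", "B"), n_per = 4, p = 12) {
  ppgrr:::.window_set(
    matrix(runif(length(ids) * n_per * p), length(ids) * n_per, p),
    data.frame(subject_id = rep(ids, each = n_per),
               window_index = seq_len(length(ids) * n_per) - 1L,
               start_s = 0, rr_true = 15,
               group = "normal", stringsAsFactors = FALSE))
}

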