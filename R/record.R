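#' @useDynLib ppgrr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx rnorm runif sd quantile cor.test predict median
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

#' Construct a PPG recording object
#'
#' A `ppg_record` bundles one subject's raw photoplethysmogram with its
#' sampling rate and a reference respiratory-rate (RR) source. Exactly one
#' reference variant must be supplied: a 1 Hz-style RR series
#' ([rr_series()]), manually keyed exhalation instants
#' ([exhalation_marks()]), or annotated breath onsets
#' ([breath_annotations()]).
#'
#' @param subject_id Non-empty identifier string.
#' @param ppg Numeric vector of PPG samples.
#' @param fs Sampling rate in Hz (positive).
#' @param duration_s Duration in seconds; `length(ppg)` must equal
#'   `round(fs * duration_s)`.
#' @param rr_reference One of `rr_series`, `exhalation_marks` or
#'   `breath_annotations`.
#' @param demographics Optional named list (age, gender, diagnosis, ...).
#' @param meta Optional named list of free-form flags (e.g. `adult`,
#'   `unlabeled`).
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(subject_id, ppg, fs, duration_s, rr_reference,
                       demographics = NULL, meta = list()) {
  if (!is.character(subject_id) || length(subject_id) != 1L ||
      is.na(subject_id) || !nzchar(subject_id)) {
    stop("`subject_id` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  ppg <- as.numeric(ppg)
  if (length(ppg) != round(fs * duration_s)) {
    stop(sprintf(
      "length(ppg) == %d but round(fs * duration_s) == %d",
      length(ppg), round(fs * duration_s)
    ), call. = FALSE)
  }
  if (!inherits(rr_reference, c("rr_series", "exhalation_marks",
                                "breath_annotations"))) {
    stop("`rr_reference` must be an rr_series, exhalation_marks or ",
         "breath_annotations object", call. = FALSE)
  }
  if (inherits(rr_reference, "exhalation_marks") &&
      length(rr_reference$times_s) > 0 &&
      (min(rr_reference$times_s) < 0 ||
       max(rr_reference$times_s) > duration_s)) {
    stop("exhalation marks must lie within [0, duration_s]", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, ppg = ppg, fs = fs,
         duration_s = duration_s, rr_reference = rr_reference,
         demographics = demographics, meta = meta),
    class = "ppg_record"
  )
}

#' Reference RR series (e.g. 1 Hz numerics channel)
#'
#' @param times_s Strictly increasing sample times in seconds.
#' @param rr_brpm Non-negative RR values in breaths per minute, same length.
#' @return An `rr_series` object.
#' @export
rr_series <- function(times_s, rr_brpm) {
  times_s <- as.numeric(times_s); rr_brpm <- as.numeric(rr_brpm)
  if (length(times_s) != length(rr_brpm)) {
    stop("`times_s` and `rr_brpm` must have equal length", call. = FALSE)
  }
  if (length(times_s) > 1 && any(diff(times_s) <= 0)) {
    stop("`times_s` must be strictly increasing", call. = FALSE)
  }
  if (any(rr_brpm < 0, na.rm = TRUE)) {
    stop("`rr_brpm` must be non-negative", call. = FALSE)
  }
  structure(list(times_s = times_s, rr_brpm = rr_brpm),
            class = "rr_series")
}

#' Exhalation keypress instants
#'
#' @param times_s Strictly increasing instants in seconds from recording
#'   start.
#' @return An `exhalation_marks` object.
#' @export
exhalation_marks <- function(times_s) {
  times_s <- as.numeric(times_s)
  if (length(times_s) > 1 && any(diff(times_s) <= 0)) {
    stop("exhalation times must be strictly increasing", call. = FALSE)
  }
  structure(list(times_s = times_s), class = "exhalation_marks")
}

#' Annotated breath onsets
#'
#' @param breath_times_s Strictly increasing onset times in seconds.
#' @return A `breath_annotations` object.
#' @export
breath_annotations <- function(breath_times_s) {
  breath_times_s <- as.numeric(breath_times_s)
  if (length(breath_times_s) > 1 && any(diff(breath_times_s) <= 0)) {
    stop("breath times must be strictly increasing", call. = FALSE)
  }
  structure(list(breath_times_s = breath_times_s),
            class = "breath_annotations")
}

#' @export
print.ppg_record <- function(x, ...) {
  ref <- class(x$rr_reference)[1]
  cat(sprintf("<ppg_record> subject %s: %.0f s @ %g Hz (%d samples), RR reference: %s\n",
              x$subject_id, x$duration_s, x$fs, length(x$ppg), ref))
  invisible(x)
}
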