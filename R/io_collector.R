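#' Read a bedside-collector JSON document
#'
#' One exported collector document describes a short bedside PPG recording
#' together with manually keyed exhalation instants (one spacebar press per
#' observed exhalation) and demographics:
#' \code{{id, demographics{gender, age, diagnosis}, fs, ppg[...],
#' exhalations_s[...]}}.
#'
#' Collections overrun the nominal two-minute core by a few seconds, so the
#' waveform and marks are truncated to the first `core_s` seconds. Marks
#' must lie within the recorded duration and be strictly increasing;
#' violations are errors. Missing demographics only warn; a document with
#' no marks loads with an empty mark set and `meta$unlabeled = TRUE`.
#'
#' @param path Path to one collector JSON document.
#' @param core_s Length of the retained recording core in seconds
#'   (default 120).
#' @return A [ppg_record()] with an [exhalation_marks()] reference.
#' @export
read_collector_record <- function(path, core_s = 120) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("format error: cannot parse %s (%s)", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  for (req in c("id", "fs", "ppg")) {
    if (is.null(doc[[req]])) {
      stop(sprintf("format error: collector document missing field '%s'",
                   req), call. = FALSE)
    }
  }
  fs <- as.numeric(doc$fs)
  ppg <- as.numeric(doc$ppg)
  raw_duration <- length(ppg) / fs
  marks <- as.numeric(doc$exhalations_s %||% numeric(0))
  meta <- list()
  if (length(marks) == 0L) {
    meta$unlabeled <- TRUE
  } else {
    if (any(marks < 0) || any(marks > raw_duration)) {
      stop("validation error: exhalation marks outside the recorded duration",
           call. = FALSE)
    }
    if (any(diff(marks) <= 0)) {
      stop("validation error: exhalation marks not strictly increasing",
           call. = FALSE)
    }
  }
  keep_s <- min(core_s, raw_duration)
  ppg <- ppg[seq_len(round(keep_s * fs))]
  marks <- marks[marks < keep_s]
  demo <- doc$demographics
  if (is.null(demo) || length(demo) == 0L) {
    warning(sprintf("collector document %s has no demographics", path),
            call. = FALSE)
    demo <- NULL
  }
  ppg_record(
    subject_id = as.character(doc$id), ppg = ppg, fs = fs,
    duration_s = keep_s, rr_reference = exhalation_marks(marks),
    demographics = as.list(demo), meta = meta
  )
}

#' Write a record as a collector JSON document
#'
#' @param record A [ppg_record()] with an `exhalation_marks` reference.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_collector_record <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  if (!inherits(record$rr_reference, "exhalation_marks")) {
    stop("collector dialect stores exhalation marks; convert first",
         call. = FALSE)
  }
  doc <- list(
    id = record$subject_id,
    demographics = record$demographics,
    fs = record$fs,
    ppg = record$ppg,
    exhalations_s = record$rr_reference$times_s
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
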