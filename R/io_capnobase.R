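#' Read a CapnoBase-dialect record (MAT container)
#'
#' The CapnoBase dialect used here stores one subject per MAT v5 container
#' with variables `ppg` (waveform), `fs` (sampling rate, Hz),
#' `breath_times_s` (annotated breath onsets in seconds) and optionally
#' `is_adult` (0/1 flag). Records are returned with a
#' [breath_annotations()] reference; the adult flag is surfaced under
#' `meta$adult` so callers can filter pediatric subjects.
#'
#' @param path MAT container path.
#' @return A [ppg_record()] with a `breath_annotations` reference.
#' @export
read_capnobase_record <- function(path) {
  vars <- tryCatch(read_mat5(path), error = function(e) {
    stop(sprintf("format error: unreadable container %s (%s)", path,
                 conditionMessage(e)), call. = FALSE)
  })
  for (req in c("ppg", "fs")) {
    if (is.null(vars[[req]])) {
      stop(sprintf("format error: container %s missing variable '%s'",
                   path, req), call. = FALSE)
    }
  }
  if (is.null(vars$breath_times_s)) {
    stop(sprintf("format error: container %s has no breath labels", path),
         call. = FALSE)
  }
  fs <- as.numeric(vars$fs)[1L]
  ppg <- as.numeric(vars$ppg)
  meta <- list()
  if (!is.null(vars$is_adult)) meta$adult <- as.numeric(vars$is_adult)[1L] != 0
  ppg_record(
    subject_id = sub("\\.mat$", "", basename(path)),
    ppg = ppg, fs = fs, duration_s = length(ppg) / fs,
    rr_reference = breath_annotations(as.numeric(vars$breath_times_s)),
    meta = meta
  )
}

#' Write a record as a CapnoBase-dialect MAT container
#'
#' @param record A [ppg_record()] with a `breath_annotations` reference.
#' @param path Output path (`.mat`).
#' @param is_adult Logical adult flag stored in the container; defaults to
#'   the record's `meta$adult` or `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_capnobase_record <- function(record, path,
                                   is_adult = isTRUE(record$meta$adult %||% TRUE)) {
  stopifnot(inherits(record, "ppg_record"))
  if (!inherits(record$rr_reference, "breath_annotations")) {
    stop("CapnoBase dialect stores breath annotations; convert first",
         call. = FALSE)
  }
  write_mat5(list(
    ppg = record$ppg,
    fs = record$fs,
    breath_times_s = record$rr_reference$breath_times_s,
    is_adult = as.numeric(is_adult)
  ), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
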