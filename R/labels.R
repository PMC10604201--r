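#' Ground-truth RR label for a time interval
#'
#' Derives the breaths-per-minute label of a half-open interval
#' `[start_s, end_s)` from whichever reference variant the record carries:
#' for an [rr_series()] the arithmetic mean (or median) of the series values
#' whose timestamps fall in the interval; for [exhalation_marks()] or
#' [breath_annotations()] the event count converted to a per-minute rate,
#' `count * 60 / (end_s - start_s)`.
#'
#' The half-open convention means an event sitting exactly on a window
#' boundary is counted once, in the window that starts there.
#'
#' @param record A [ppg_record()].
#' @param start_s,end_s Interval bounds, `0 <= start_s < end_s <=
#'   duration_s`.
#' @param stat Summary for `rr_series` references: `"mean"` (default) or
#'   `"median"`.
#' @return RR in breaths per minute (non-negative scalar).
#' @export
rr_label_for_interval <- function(record, start_s, end_s, stat = c("mean", "median")) {
  stopifnot(inherits(record, "ppg_record"))
  stat <- match.arg(stat)
  if (!(start_s >= 0 && start_s < end_s && end_s <= record$duration_s)) {
    stop("require 0 <= start_s < end_s <= duration_s", call. = FALSE)
  }
  ref <- record$rr_reference
  if (inherits(ref, "rr_series")) {
    keep <- ref$times_s >= start_s & ref$times_s < end_s
    vals <- ref$rr_brpm[keep]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) {
      stop(sprintf("no finite RR reference samples in [%g, %g)", start_s, end_s),
           call. = FALSE)
    }
    if (stat == "mean") mean(vals) else median(vals)
  } else {
    times <- if (inherits(ref, "exhalation_marks")) ref$times_s else ref$breath_times_s
    n <- sum(times >= start_s & times < end_s)
    n * 60 / (end_s - start_s)
  }
}
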