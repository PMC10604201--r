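#' Read a BIDMC-dialect record (paired Signals/Numerics CSV)
#'
#' The BIDMC dialect stores one subject as two CSV tables: a high-rate
#' signals table (`<prefix>_Signals.csv`) whose columns include a `PLETH`
#' photoplethysmogram channel and a `Time [s]` column, and a 1 Hz numerics
#' table (`<prefix>_Numerics.csv`) with a `RESP` respiratory-rate column in
#' breaths per minute.
#'
#' A record whose `RESP` column contains no finite value at all is rejected
#' (exclusion error), matching the practice of dropping monitor exports with
#' a dead RR channel. Partially missing 1 Hz samples are linearly
#' interpolated with a warning.
#'
#' @param path Path to the `*_Signals.csv` file, or the common prefix of the
#'   pair (the `_Signals.csv` / `_Numerics.csv` suffixes are appended).
#' @param exclude Optional hook `function(record) TRUE/FALSE`; records for
#'   which it returns `TRUE` are rejected with an exclusion error. Lets
#'   callers encode cohort-specific exclusion rules without the reader
#'   guessing any.
#' @return A [ppg_record()] with an [rr_series()] reference.
#' @export
read_bidmc_record <- function(path, exclude = NULL) {
  if (grepl("_Signals\\.csv$", path)) {
    prefix <- sub("_Signals\\.csv$", "", path)
  } else if (grepl("_Numerics\\.csv$", path)) {
    prefix <- sub("_Numerics\\.csv$", "", path)
  } else {
    prefix <- path
  }
  sig_path <- paste0(prefix, "_Signals.csv")
  num_path <- paste0(prefix, "_Numerics.csv")
  for (p in c(sig_path, num_path)) {
    if (!file.exists(p)) {
      stop(sprintf("BIDMC pair member not found: %s", p), call. = FALSE)
    }
  }
  sig <- .read_bidmc_table(sig_path)
  num <- .read_bidmc_table(num_path)
  pleth_col <- .find_column(sig, "PLETH", sig_path)
  time_col <- .find_column(sig, "Time", sig_path)
  resp_col <- .find_column(num, "RESP", num_path)
  ntime_col <- .find_column(num, "Time", num_path)

  ppg <- as.numeric(sig[[pleth_col]])
  t_sig <- as.numeric(sig[[time_col]])
  if (length(ppg) < 2L) stop("signals table is empty", call. = FALSE)
  fs <- round(1 / median(diff(t_sig)))
  duration_s <- length(ppg) / fs

  rr <- as.numeric(num[[resp_col]])
  t_rr <- as.numeric(num[[ntime_col]])
  if (!any(is.finite(rr))) {
    stop(sprintf("record %s excluded: RR reference entirely missing",
                 basename(prefix)), call. = FALSE)
  }
  if (anyNA(rr) || any(!is.finite(rr))) {
    bad <- !is.finite(rr)
    rr[bad] <- approx(t_rr[!bad], rr[!bad], xout = t_rr[bad], rule = 2)$y
    warning(sprintf("record %s: %d missing RR samples linearly interpolated",
                    basename(prefix), sum(bad)), call. = FALSE)
  }
  rec <- ppg_record(
    subject_id = basename(prefix), ppg = ppg, fs = fs,
    duration_s = duration_s, rr_reference = rr_series(t_rr, rr)
  )
  if (!is.null(exclude) && isTRUE(exclude(rec))) {
    stop(sprintf("record %s excluded by exclusion hook", basename(prefix)),
         call. = FALSE)
  }
  rec
}

.read_bidmc_table <- function(path) {
  out <- tryCatch(
    read.csv(path, check.names = FALSE, strip.white = TRUE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (nrow(out) == 0L || ncol(out) == 0L) {
    stop(sprintf("format error: %s is empty", path), call. = FALSE)
  }
  out
}

.find_column <- function(df, key, path) {
  nm <- trimws(names(df))
  hit <- which(toupper(nm) == toupper(key) |
                 grepl(paste0("^", key), nm, ignore.case = TRUE))
  if (length(hit) == 0L) {
    stop(sprintf("format error: column '%s' missing from %s", key, path),
         call. = FALSE)
  }
  names(df)[hit[1L]]
}

#' Write a record as a BIDMC-dialect CSV pair
#'
#' Inverse of [read_bidmc_record()] for records carrying an [rr_series()]
#' reference. Values are written with 17 significant digits so a write/read
#' round trip reproduces the PPG samples bit-exactly.
#'
#' @param record A [ppg_record()] with an `rr_series` reference.
#' @param dir Output directory (created if absent).
#' @param prefix File prefix; defaults to the subject id.
#' @return Invisibly, the signals-file path.
#' @export
write_bidmc_record <- function(record, dir, prefix = record$subject_id) {
  stopifnot(inherits(record, "ppg_record"))
  if (!inherits(record$rr_reference, "rr_series")) {
    stop("BIDMC dialect stores an RR series reference; convert first",
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig_path <- file.path(dir, paste0(prefix, "_Signals.csv"))
  num_path <- file.path(dir, paste0(prefix, "_Numerics.csv"))
  t_sig <- seq_along(record$ppg) - 1
  writeLines(c("Time [s], PLETH",
               sprintf("%.17g,%.17g", t_sig / record$fs, record$ppg)),
             sig_path)
  ref <- record$rr_reference
  writeLines(c("Time [s], RESP",
               sprintf("%.17g,%.17g", ref$times_s, ref$rr_brpm)),
             num_path)
  invisible(sig_path)
}
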