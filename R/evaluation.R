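# Breathing-group-stratified evaluation: MAE, Bland-Altman agreement,
# Pearson correlation, box-plot five-number summaries with 1.5*IQR
# outlier counts, and SNR robustness tables.

#' Mean absolute error
#'
#' `(1/N) * sum(|rr_true - rr_est|)` in breaths per minute.
#'
#' @param rr_true,rr_est Equal-length numeric vectors.
#' @return Scalar MAE.
#' @export
mae <- function(rr_true, rr_est) {
  if (length(rr_true) != length(rr_est)) {
    stop("shape error: rr_true and rr_est must have equal length",
         call. = FALSE)
  }
  if (length(rr_true) == 0L) stop("empty input", call. = FALSE)
  mean(abs(rr_true - rr_est))
}

#' Mean and standard deviation of per-fold MAEs
#'
#' @param fold_maes Numeric vector of per-fold MAE values.
#' @return `list(mean, sd, single_fold)`; with one fold the SD is
#'   undefined and reported as 0 with `single_fold = TRUE`.
#' @export
mae_sd <- function(fold_maes) {
  if (length(fold_maes) == 0L) stop("no folds", call. = FALSE)
  if (length(fold_maes) == 1L) {
    return(list(mean = fold_maes, sd = 0, single_fold = TRUE))
  }
  list(mean = mean(fold_maes), sd = sd(fold_maes), single_fold = FALSE)
}

#' Stratified evaluation report
#'
#' Computes, for each breathing group and overall: MAE with the
#' across-window SD of absolute errors; plus overall Pearson correlation
#' (two-sided test), Bland-Altman bias and 1.96*SD limits of agreement of
#' `est - true`, the five-number summary (min, q1, median, q3, max;
#' type-7 quantiles) of absolute errors, and the count of box-plot
#' outliers (points beyond 1.5*IQR from the quartiles).
#'
#' @param windows A `window_set` (or a data.frame with `rr_true` and
#'   `group` columns).
#' @param rr_est Estimates aligned with the windows.
#' @return An `eval_report` list; empty groups are reported as absent
#'   (`NA`), not zero.
#' @export
stratified_report <- function(windows, rr_est) {
  meta <- if (inherits(windows, "window_set")) windows$meta else windows
  if (nrow(meta) != length(rr_est)) {
    stop("shape error: estimates not aligned with windows", call. = FALSE)
  }
  rr_true <- meta$rr_true
  grp <- meta$group
  abs_err <- abs(rr_true - rr_est)
  per_group <- do.call(rbind, lapply(c("slow", "normal", "rapid", "all"),
                                     function(g) {
    keep <- if (g == "all") rep(TRUE, length(grp)) else grp == g
    if (!any(keep)) {
      return(data.frame(group = g, n = 0L, mae = NA_real_, sd = NA_real_))
    }
    data.frame(group = g, n = sum(keep), mae = mean(abs_err[keep]),
               sd = if (sum(keep) > 1) sd(abs_err[keep]) else 0)
  }))

  diffs <- rr_est - rr_true
  bias <- mean(diffs)
  loa_half <- 1.96 * sd(diffs)
  if (sd(rr_true) == 0 || sd(rr_est) == 0) {
    pearson <- list(r = NA_real_, p = NA_real_, constant_input = TRUE)
  } else {
    ct <- cor.test(rr_true, rr_est, alternative = "two.sided")
    pearson <- list(r = unname(ct$estimate), p = ct$p.value,
                    constant_input = FALSE)
  }
  q <- unname(quantile(abs_err, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  iqr <- q[4] - q[2]
  out_mask <- abs_err > q[4] + 1.5 * iqr | abs_err < q[2] - 1.5 * iqr
  structure(list(
    per_group = per_group,
    pearson = pearson,
    bland_altman = c(bias = bias, loa_lower = bias - loa_half,
                     loa_upper = bias + loa_half),
    fivenum = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]),
    outliers = c(count = sum(out_mask), fraction = mean(out_mask)),
    n = length(abs_err)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d windows\n", x$n))
  df <- x$per_group
  df$mae <- sprintf("%.4f", df$mae)
  df$sd <- sprintf("%.4f", df$sd)
  print(df, row.names = FALSE)
  if (!isTRUE(x$pearson$constant_input)) {
    cat(sprintf("Pearson r = %.4f (p = %.3g)\n", x$pearson$r, x$pearson$p))
  } else {
    cat("Pearson r undefined (constant input)\n")
  }
  cat(sprintf("Bland-Altman bias %.4f, LoA [%.4f, %.4f]\n",
              x$bland_altman["bias"], x$bland_altman["loa_lower"],
              x$bland_altman["loa_upper"]))
  cat(sprintf("abs-error five-number: %s\n",
              paste(sprintf("%.4f", x$fivenum), collapse = " / ")))
  cat(sprintf("outliers: %d (%.2f%%)\n", x$outliers["count"],
              100 * x$outliers["fraction"]))
  invisible(x)
}

#' Group-level MAE accessor
#' @param report An `eval_report`.
#' @param group One of `"slow"`, `"normal"`, `"rapid"`, `"all"`.
#' @return The group MAE (NA if the group was absent).
#' @export
report_mae <- function(report, group = "all") {
  report$per_group$mae[report$per_group$group == group]
}

#' SNR robustness table
#'
#' Re-runs the preprocessing-and-predict pipeline on artifact-injected
#' copies of the clean test records at each requested SNR level and
#' reports the MAE per level. The `"Original"` row is the clean,
#' uninjected pipeline.
#'
#' @param estimator A trained estimator.
#' @param records Clean test [ppg_record()]s (artifacts are injected on
#'   the raw records; the standard pipeline then runs).
#' @param snr_levels Numeric dB levels (e.g. `c(20, 15, 10)`).
#' @param seed Base seed for the artifact draws (one derived seed per
#'   level).
#' @param wspec,fspec Preprocessing specifications.
#' @param artifact_band_hz Artifact band passed to [snr_spec()].
#' @return data.frame with `level`, `snr_db`, `mae`, `sd_abs_err`, `n`.
#' @export
snr_robustness <- function(estimator, records, snr_levels = c(20, 15, 10),
                           seed = 1L, wspec = window_spec(),
                           fspec = filter_spec(),
                           artifact_band_hz = c(0.05, 1.0)) {
  level_seeds <- .with_seed(seed,
                            sample.int(.Machine$integer.max - 1L,
                                       length(snr_levels) * length(records)))
  eval_at <- function(recs) {
    ws <- preprocess_records(recs, wspec, fspec)
    err <- abs(ws$meta$rr_true - predict(estimator, ws))
    c(mae = mean(err), sd = sd(err), n = length(err))
  }
  rows <- list(cbind(data.frame(level = "Original", snr_db = Inf),
                     as.data.frame(t(eval_at(records)))))
  for (i in seq_along(snr_levels)) {
    noisy <- lapply(seq_along(records), function(j) {
      sp <- snr_spec(snr_levels[i], artifact_band_hz = artifact_band_hz,
                     seed = level_seeds[(i - 1L) * length(records) + j])
      inject_artifact_to_snr(records[[j]], sp)
    })
    rows <- c(rows, list(cbind(
      data.frame(level = sprintf("%g db", snr_levels[i]),
                 snr_db = snr_levels[i]),
      as.data.frame(t(eval_at(noisy))))))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("level", "snr_db", "mae", "sd_abs_err", "n")
  rownames(out) <- NULL
  out
}

#' Write a results table as CSV and Markdown
#'
#' @param df A data.frame (models or SNR levels in rows).
#' @param csv_path,md_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, `df`.
#' @export
write_report_table <- function(df, csv_path = NULL, md_path = NULL) {
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.4f", col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
               apply(fmt, 1L, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, md_path)
  }
  invisible(df)
}
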