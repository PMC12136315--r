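# Infusion-deviation statistics: single/mean/max deviation of bolus logs,
# cumulative deviation of basal-rate runs, and paired t-tests comparing
# pump variants.

#' Build an infusion log
#'
#' @param commanded_dose_U Commanded (theoretical) dose per infusion, U;
#'   must be positive.
#' @param delivered_dose_U Measured delivered dose, U (typically the mean of
#'   repeated weighings); must be non-negative.
#' @param index Optional event indices (default sequential).
#' @param timestamp Optional timestamps.
#' @return A data frame of class `infusion_log` with columns `index`,
#'   `commanded_dose_U`, `delivered_dose_U` (and `timestamp` if given).
#' @export
infusion_log <- function(commanded_dose_U, delivered_dose_U,
                         index = seq_along(commanded_dose_U),
                         timestamp = NULL) {
  if (length(commanded_dose_U) != length(delivered_dose_U)) {
    stop("commanded and delivered doses must have equal length",
         call. = FALSE)
  }
  if (any(commanded_dose_U <= 0)) {
    stop("`commanded_dose_U` must be positive", call. = FALSE)
  }
  if (any(delivered_dose_U < 0)) {
    stop("`delivered_dose_U` must be non-negative", call. = FALSE)
  }
  out <- data.frame(index = index,
                    commanded_dose_U = commanded_dose_U,
                    delivered_dose_U = delivered_dose_U)
  if (!is.null(timestamp)) out$timestamp <- timestamp
  class(out) <- c("infusion_log", "data.frame")
  out
}

#' Single infusion deviation
#'
#' Percent deviation of one delivery:
#' `|theoretical - actual| / theoretical * 100`. The absolute-value
#' convention is the default because bench over-deliveries must count
#' against accuracy the same way under-deliveries do (aggregate
#' maximum/mean figures only reconcile under `|.|`); set `signed = TRUE`
#' for the raw signed deviation.
#'
#' @param theoretical Commanded dose, U; must be positive.
#' @param actual Delivered dose, U.
#' @param signed If `TRUE`, return the signed deviation (positive =
#'   under-delivery).
#' @return Deviation in percent. Vectorised.
#' @examples
#' single_deviation(1.00, 0.96)  # 4
#' @export
single_deviation <- function(theoretical, actual, signed = FALSE) {
  if (any(theoretical <= 0)) {
    stop("`theoretical` dose must be positive", call. = FALSE)
  }
  d <- (theoretical - actual) / theoretical * 100
  if (signed) d else abs(d)
}

#' Mean deviation
#'
#' Arithmetic mean of single-infusion percent deviations.
#'
#' @param deviations Non-empty numeric vector of percent deviations.
#' @return Mean deviation, percent.
#' @export
mean_deviation <- function(deviations) {
  if (length(deviations) == 0) {
    stop("`deviations` must be non-empty", call. = FALSE)
  }
  mean(deviations)
}

#' Deviation report for an infusion log
#'
#' Applies [single_deviation()] per record and aggregates by maximum,
#' minimum and mean. Unrounded values are retained; rounding to two decimals
#' happens only in printing/CSV export.
#'
#' @param log An [infusion_log()] (or data frame with `commanded_dose_U`
#'   and `delivered_dose_U`).
#' @param signed Passed to [single_deviation()].
#' @return List of class `deviation_report` with `per_record_deviation_pct`,
#'   `max_deviation_pct`, `min_deviation_pct`, `mean_deviation_pct`, `n`.
#' @export
deviation_report <- function(log, signed = FALSE) {
  if (nrow(log) == 0) stop("empty infusion log", call. = FALSE)
  d <- single_deviation(log$commanded_dose_U, log$delivered_dose_U,
                        signed = signed)
  structure(
    list(per_record_deviation_pct = d,
         max_deviation_pct = max(d),
         min_deviation_pct = min(d),
         mean_deviation_pct = mean_deviation(d),
         n = length(d)),
    class = "deviation_report"
  )
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("Deviation over %d infusions: max %.2f%%, min %.2f%%, mean %.2f%%\n",
              x$n, x$max_deviation_pct, x$min_deviation_pct,
              x$mean_deviation_pct))
  invisible(x)
}

#' Cumulative basal-rate deviation report
#'
#' Scores a continuous basal run weighed at read times: the theoretical
#' cumulative dose at time `t` is `rate * t` exactly, and the total
#' deviation is `|rate*t - cumulative| / (rate*t) * 100` at every read.
#'
#' @param rate_U_per_h Programmed basal rate, U/h.
#' @param time_h Read times, hours; strictly increasing and positive.
#' @param cumulative_U Cumulative delivered dose at each read, U;
#'   non-decreasing.
#' @return Data frame of class `basal_run_report` with columns `time_h`,
#'   `cumulative_actual_U`, `cumulative_theoretical_U`,
#'   `total_deviation_pct`.
#' @examples
#' basal_run_report(0.5, 6, 2.87)  # 4.33%
#' @export
basal_run_report <- function(rate_U_per_h, time_h, cumulative_U) {
  if (length(time_h) != length(cumulative_U) || length(time_h) == 0) {
    stop("`time_h` and `cumulative_U` must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(time_h <= 0) || is.unsorted(time_h, strictly = TRUE)) {
    stop("`time_h` must be positive and strictly increasing", call. = FALSE)
  }
  if (is.unsorted(cumulative_U)) {
    stop("`cumulative_U` must be non-decreasing", call. = FALSE)
  }
  theo <- rate_U_per_h * time_h
  out <- data.frame(
    time_h = time_h,
    cumulative_actual_U = cumulative_U,
    cumulative_theoretical_U = theo,
    total_deviation_pct = abs(theo - cumulative_U) / theo * 100
  )
  class(out) <- c("basal_run_report", "data.frame")
  out
}

t_result <- function(n, mean_diff, sd_diff) {
  se <- sd_diff / sqrt(n)
  df <- n - 1
  if (se == 0) {
    t <- if (mean_diff == 0) 0 else Inf * sign(mean_diff)
    p <- if (mean_diff == 0) 1 else 0
    half <- 0
  } else {
    t <- mean_diff / se
    p <- 2 * stats::pt(-abs(t), df)
    half <- stats::qt(0.975, df) * se
  }
  structure(
    list(n_pairs = n, mean_difference = mean_diff, sd_difference = sd_diff,
         se_mean = se, t_statistic = t, degrees_of_freedom = df,
         p_value = p, ci95_low = mean_diff - half, ci95_high = mean_diff + half),
    class = "paired_t_result"
  )
}

#' Paired t-test
#'
#' Classical paired t-test on `a - b`: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `n - 1` degrees of freedom, two-sided p-value and symmetric 95%
#' confidence interval. When every difference is identical and non-zero the
#' statistic is reported as a signed infinity with `p = 0`.
#'
#' @param a,b Equal-length numeric vectors (length >= 2) of paired
#'   measurements (e.g. mean deviations of two pump variants at matched
#'   doses).
#' @return List of class `paired_t_result` with fields `n_pairs`,
#'   `mean_difference`, `sd_difference`, `se_mean`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `ci95_low`, `ci95_high`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("`a` and `b` must be equal-length with n >= 2", call. = FALSE)
  }
  d <- a - b
  t_result(length(d), mean(d), stats::sd(d))
}

#' Paired t-test from summary statistics
#'
#' Same contract as [paired_t_test()] when only the summary of the paired
#' differences is available (sample size, mean and standard deviation of
#' the differences) — the form in which bench comparisons are usually
#' reported.
#'
#' @param n Number of pairs (>= 2).
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Standard deviation of the differences (>= 0).
#' @return A `paired_t_result`.
#' @examples
#' t_test_from_summary(10, 0.35300, 0.35923)  # t = 3.107, p = 0.013
#' @export
t_test_from_summary <- function(n, mean_diff, sd_diff) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (sd_diff < 0) stop("`sd_diff` must be >= 0", call. = FALSE)
  t_result(n, mean_diff, sd_diff)
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: n = %d, mean diff = %.5f (sd %.5f, se %.5f)\n",
    x$n_pairs, x$mean_difference, x$sd_difference, x$se_mean))
  cat(sprintf("  t = %.3f, df = %d, p = %.3f, 95%% CI [%.5f, %.5f]\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Read / write infusion-log CSV
#'
#' Infusion logs travel as CSV with columns `index`, `commanded_dose_U`,
#' `delivered_dose_U` and optionally `timestamp`; basal runs as `time_h`,
#' `cumulative_U`.
#'
#' @param path CSV path.
#' @return `read_infusion_csv()`: an [infusion_log()].
#' @export
read_infusion_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("commanded_dose_U", "delivered_dose_U")
  if (!all(need %in% names(df))) {
    stop("infusion CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  infusion_log(df$commanded_dose_U, df$delivered_dose_U,
               index = if ("index" %in% names(df)) df$index else
                 seq_len(nrow(df)),
               timestamp = df$timestamp)
}

#' @rdname read_infusion_csv
#' @param log An [infusion_log()].
#' @export
write_infusion_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a deviation or basal report to CSV
#'
#' Percent columns are rounded half-away-from-zero to two decimals for
#' display, mirroring bench-report conventions; computation keeps full
#' precision.
#'
#' @param report A `deviation_report` or `basal_run_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
  if (inherits(report, "deviation_report")) {
    df <- data.frame(
      statistic = c("max_deviation_pct", "min_deviation_pct",
                    "mean_deviation_pct"),
      value = round2(c(report$max_deviation_pct, report$min_deviation_pct,
                       report$mean_deviation_pct))
    )
  } else if (inherits(report, "basal_run_report")) {
    df <- as.data.frame(report)
    df$total_deviation_pct <- round2(df$total_deviation_pct)
  } else {
    stop("unsupported report type", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
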