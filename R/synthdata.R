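# Seeded generators for infusion logs, basal runs and deviation series with
# the statistical texture the analysis assumes (systematic under-delivery
# bias, slow drift, Gaussian weighing noise), plus verbatim fixtures of the
# published bench tables used in regression tests.

#' Generator specification
#'
#' Parameters of the synthetic infusion-log generator. Defaults emulate a
#' bench run of repeated 2 U infusions with a mean under-delivery of 3.5% of
#' the commanded dose — the middle of the 2–6% range typical of plunger
#' pumps at these doses — no drift, and 0.01 U (1%-of-dose) weighing noise.
#'
#' @param n_infusions Number of infusion events.
#' @param commanded_dose_U Commanded dose per event, U.
#' @param bias_fraction Mean under-delivery as a fraction of the commanded
#'   dose, in `[0, 1)`.
#' @param drift_per_infusion_U Additional under-delivery accumulating
#'   linearly with event index (e.g. reservoir-pressure decay), U/event.
#' @param noise_sd_U Standard deviation of Gaussian measurement/delivery
#'   noise, U.
#' @param seed Seed; every generator is bit-reproducible under it.
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(n_infusions = 120, commanded_dose_U = 2,
                           bias_fraction = 0.035,
                           drift_per_infusion_U = 0,
                           noise_sd_U = 0.01, seed = 1L) {
  if (noise_sd_U < 0) stop("`noise_sd_U` must be >= 0", call. = FALSE)
  if (bias_fraction < 0 || bias_fraction >= 1) {
    stop("`bias_fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_infusions = as.integer(n_infusions),
         commanded_dose_U = commanded_dose_U,
         bias_fraction = bias_fraction,
         drift_per_infusion_U = drift_per_infusion_U,
         noise_sd_U = noise_sd_U, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

#' Generate a synthetic infusion log
#'
#' Delivered dose per event `i` is
#' `commanded * (1 - bias) - drift * i + N(0, noise_sd)`, clipped at zero.
#'
#' @param spec A [generator_spec()].
#' @return An [infusion_log()].
#' @export
generate_infusions <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    idx <- seq_len(spec$n_infusions)
    delivered <- spec$commanded_dose_U * (1 - spec$bias_fraction) -
      spec$drift_per_infusion_U * idx +
      stats::rnorm(spec$n_infusions, 0, spec$noise_sd_U)
    infusion_log(rep(spec$commanded_dose_U, spec$n_infusions),
                 pmax(delivered, 0), index = idx)
  })
}

#' Simulate delivery of arbitrary commanded doses
#'
#' Same delivery model as [generate_infusions()] but for caller-supplied
#' commanded doses — used to re-simulate delivery after a compensation plan
#' has inflated the commands.
#'
#' @param commanded_dose_U Vector of commanded doses, U.
#' @param spec A [generator_spec()] supplying bias/drift/noise/seed
#'   (its `n_infusions` and `commanded_dose_U` fields are ignored).
#' @return An [infusion_log()] with the supplied commands.
#' @export
simulate_delivery <- function(commanded_dose_U, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    idx <- seq_along(commanded_dose_U)
    delivered <- commanded_dose_U * (1 - spec$bias_fraction) -
      spec$drift_per_infusion_U * idx +
      stats::rnorm(length(idx), 0, spec$noise_sd_U)
    infusion_log(commanded_dose_U, pmax(delivered, 0), index = idx)
  })
}

#' Generate a synthetic basal-rate run
#'
#' Simulates continuous delivery at `rate_U_per_h` with the spec's
#' under-delivery bias and per-interval Gaussian noise, read at a balance
#' every `read_interval_h`. Cumulative readings are non-decreasing by
#' construction (per-interval deliveries are clipped at zero).
#'
#' @param rate_U_per_h Programmed basal rate, U/h.
#' @param hours Run length, h.
#' @param read_interval_h Interval between balance reads, h.
#' @param spec A [generator_spec()] (bias/noise/seed).
#' @return Data frame with `time_h` and `cumulative_U`.
#' @export
generate_basal_run <- function(rate_U_per_h = 0.5, hours = 24,
                               read_interval_h = 0.5,
                               spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- as.integer(round(hours / read_interval_h))
  with_seed(spec$seed, {
    per <- rate_U_per_h * read_interval_h * (1 - spec$bias_fraction) +
      stats::rnorm(n, 0, spec$noise_sd_U)
    data.frame(time_h = read_interval_h * seq_len(n),
               cumulative_U = cumsum(pmax(per, 0)))
  })
}

# Published single-dose bench table: 10 repeats each of 1-10 U commands,
# delivered doses as printed, plus the printed max/mean deviation columns.
table2_data <- function() {
  actual <- rbind(
    c(0.96, 0.96, 0.97, 0.96, 0.97, 0.98, 0.96, 0.96, 0.98, 0.97),
    c(1.91, 1.91, 1.90, 1.94, 1.92, 1.93, 1.91, 2.00, 1.93, 1.91),
    c(2.91, 2.89, 2.89, 3.01, 3.01, 2.97, 2.98, 2.89, 2.91, 2.93),
    c(3.92, 3.91, 3.92, 3.83, 3.91, 3.94, 3.92, 3.91, 3.91, 4.01),
    c(4.87, 4.78, 4.91, 4.82, 4.78, 4.87, 4.93, 5.01, 4.91, 4.91),
    c(5.89, 5.78, 5.90, 5.81, 5.79, 5.81, 5.83, 5.88, 6.02, 5.82),
    c(6.79, 6.71, 6.77, 6.79, 6.80, 6.81, 6.81, 6.83, 6.81, 6.79),
    c(7.73, 7.61, 7.62, 7.70, 7.63, 7.65, 7.69, 7.91, 7.74, 7.81),
    c(8.63, 8.61, 8.59, 8.76, 8.73, 9.02, 8.72, 8.67, 8.86, 8.79),
    c(9.72, 9.61, 9.75, 10.31, 9.73, 9.71, 9.72, 9.64, 9.68, 9.61))
  data.frame(
    set_dose_U = rep(1:10, each = 10),
    repeat_no = rep(1:10, times = 10),
    actual_dose_U = as.vector(t(actual)),
    printed_max_deviation_pct = rep(
      c(4.00, 4.50, 3.67, 4.25, 4.40, 3.67, 4.14, 4.87, 4.56, 3.90),
      each = 10),
    printed_mean_deviation_pct = rep(
      c(3.30, 3.70, 2.77, 4.13, 2.46, 2.85, 2.98, 3.64, 3.19, 3.14),
      each = 10)
  )
}

# Published 24 h basal-rate bench table at 0.5 U/h: cumulative dose and
# printed total deviation for the one- and two-stage drives at 14 read nodes.
table4_data <- function() {
  data.frame(
    time_h = c(0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24),
    one_stage_cumulative_U = c(0.23, 0.47, 0.94, 1.89, 2.87, 3.78, 4.76,
                               5.73, 6.73, 7.67, 8.60, 9.54, 10.61, 11.57),
    two_stage_cumulative_U = c(0.23, 0.47, 0.96, 1.92, 2.89, 3.81, 4.79,
                               5.75, 6.78, 7.72, 8.67, 9.63, 10.71, 11.62),
    one_stage_printed_deviation_pct = c(8.00, 6.00, 6.00, 5.50, 4.33, 5.50,
                                        4.80, 4.50, 3.86, 4.13, 4.44, 4.60,
                                        3.55, 3.58),
    two_stage_printed_deviation_pct = c(8.00, 6.00, 4.00, 4.00, 3.67, 4.75,
                                        4.20, 4.17, 3.14, 3.50, 3.67, 3.70,
                                        2.64, 3.12)
  )
}

#' Published bench-table fixtures
#'
#' Returns the printed single-dose accuracy table (`"table2"`: 10 repeats of
#' each 1–10 U command with the published max/mean deviation columns) or the
#' 24 h, 0.5 U/h basal-rate table (`"table4"`: 14 read nodes with cumulative
#' doses and printed total deviations for both drive variants), verbatim,
#' for regression tests against the published statistics.
#'
#' @param name `"table2"` or `"table4"`.
#' @return A data frame.
#' @export
table_fixture <- function(name = c("table2", "table4")) {
  name <- match.arg(name)
  switch(name, table2 = table2_data(), table4 = table4_data())
}
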