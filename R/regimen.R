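# Dose-regimen arithmetic: total daily insulin requirement and the
# basal/bolus schedule that delivers it.

#' Total daily insulin requirement
#'
#' Estimates the total daily insulin dose for an insulin-naive patient from
#' body weight and fasting blood glucose using the weight-scaled excess-glucose
#' rule `U = 6 * K * (P - 100) / 2000`, where `K` is body weight in kg, `P` is
#' fasting glucose in mg/dL and 100 mg/dL is the normal fasting reference.
#' The result is in insulin units (U).
#'
#' @param weight_kg Body weight in kilograms; must be positive.
#' @param fasting_glucose_mgdl Fasting blood glucose in mg/dL; must be at
#'   least 100 (values below the reference would give a clinically
#'   meaningless negative dose and are rejected).
#' @return Total daily insulin dose in units (U).
#' @examples
#' daily_insulin_requirement(75, 220)  # 27 U
#' @export
daily_insulin_requirement <- function(weight_kg, fasting_glucose_mgdl) {
  stopifnot(is.numeric(weight_kg), is.numeric(fasting_glucose_mgdl))
  if (any(weight_kg <= 0)) {
    stop("`weight_kg` must be positive", call. = FALSE)
  }
  if (any(fasting_glucose_mgdl < 100)) {
    stop("`fasting_glucose_mgdl` below the 100 mg/dL reference yields a ",
         "non-positive dose and is rejected", call. = FALSE)
  }
  6 * weight_kg * (fasting_glucose_mgdl - 100) / 2000
}

# "HH:MM" -> minutes since midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("clock times must be \"HH:MM\"", call. = FALSE)
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

format_clock <- function(minutes) {
  minutes <- minutes %% 1440
  sprintf("%02d:%02d", minutes %/% 60, round(minutes %% 60))
}

# window length in minutes, wrapping at midnight (e.g. 20:00-1:00 = 5 h)
window_minutes <- function(start_min, end_min) {
  len <- (end_min - start_min) %% 1440
  if (len == 0) stop("zero-length time window", call. = FALSE)
  len
}

#' Build a daily basal/bolus infusion regimen
#'
#' Splits a total daily dose into pre-meal boluses and continuous basal
#' windows. The bolus share `total * (1 - basal_fraction)` is divided equally
#' across `bolus_count` boluses; the basal share is divided equally across the
#' supplied basal time windows and delivered as one small dose every
#' `basal_interval` minutes within each window. Doses are conserved exactly:
#' the scheduled events always sum back to `total`.
#'
#' Time windows wrap at midnight, so a window from `"20:00"` to `"01:00"`
#' is five hours long.
#'
#' @param total Total daily insulin dose (U), e.g. from
#'   [daily_insulin_requirement()].
#' @param basal_fraction Fraction of `total` delivered as basal, strictly
#'   between 0 and 1. Published presets put this anywhere between 0.4 and 0.6;
#'   the worked 27 U example uses 15/27.
#' @param bolus_count Number of pre-meal boluses (>= 1).
#' @param basal_windows List of `c(start, end)` pairs of `"HH:MM"` clock
#'   times (or minutes since midnight) for the basal windows.
#' @param basal_interval Minutes between basal micro-doses; every window
#'   length must be an exact multiple of it.
#' @param bolus_windows Optional list of `c(start, end)` pairs for the
#'   boluses; defaults to unspecified (events placed at window starts when
#'   given, otherwise at hour 0).
#' @param bolus_event_dose Optional size (U) of the individual events a bolus
#'   is delivered in; each bolus must be an exact multiple of it. `NULL`
#'   delivers each bolus as a single event.
#' @return An object of class `daily_regimen`: a list with `total_U`,
#'   `basal_fraction` and a `segments` data frame (one row per segment with
#'   mode, start/end clock, total dose, per-event dose and event count).
#' @seealso [regimen_events()] to expand the regimen into individual events,
#'   [table1_regimen()] for the shipped 27 U worked example.
#' @export
build_regimen <- function(total, basal_fraction, bolus_count,
                          basal_windows, basal_interval,
                          bolus_windows = NULL, bolus_event_dose = NULL) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0) {
    stop("`total` must be a single positive dose", call. = FALSE)
  }
  if (!is.numeric(basal_fraction) || length(basal_fraction) != 1L ||
      basal_fraction <= 0 || basal_fraction >= 1) {
    stop("`basal_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (bolus_count < 1) stop("`bolus_count` must be >= 1", call. = FALSE)
  if (length(basal_windows) < 1L) {
    stop("at least one basal window is required", call. = FALSE)
  }

  basal_total <- total * basal_fraction
  bolus_total <- total - basal_total
  bolus_dose <- bolus_total / bolus_count
  basal_window_dose <- basal_total / length(basal_windows)

  segs <- list()
  for (k in seq_len(bolus_count)) {
    win <- if (!is.null(bolus_windows)) bolus_windows[[k]] else c(0, 0)
    start <- parse_clock(win[1])
    n_events <- 1L
    if (!is.null(bolus_event_dose)) {
      ratio <- bolus_dose / bolus_event_dose
      if (abs(ratio - round(ratio)) > 1e-9) {
        stop("bolus dose ", bolus_dose, " U is not a multiple of ",
             "`bolus_event_dose`", call. = FALSE)
      }
      n_events <- as.integer(round(ratio))
    }
    segs[[length(segs) + 1L]] <- data.frame(
      mode = "bolus",
      start_min = start,
      end_min = parse_clock(win[2]),
      total_dose_U = bolus_dose,
      event_dose_U = bolus_dose / n_events,
      n_events = n_events
    )
  }
  for (win in basal_windows) {
    start <- parse_clock(win[1])
    end <- parse_clock(win[2])
    len <- window_minutes(start, end)
    n_events <- len / basal_interval
    if (abs(n_events - round(n_events)) > 1e-9) {
      stop("basal window length ", len, " min is not divisible by the ",
           basal_interval, " min interval", call. = FALSE)
    }
    n_events <- as.integer(round(n_events))
    segs[[length(segs) + 1L]] <- data.frame(
      mode = "basal",
      start_min = start,
      end_min = end,
      total_dose_U = basal_window_dose,
      event_dose_U = basal_window_dose / n_events,
      n_events = n_events
    )
  }
  segments <- do.call(rbind, segs)
  segments$start <- format_clock(segments$start_min)
  segments$end <- format_clock(segments$end_min)

  structure(
    list(total_U = total, basal_fraction = basal_fraction,
         segments = segments),
    class = "daily_regimen"
  )
}

#' @export
print.daily_regimen <- function(x, ...) {
  cat(sprintf("Daily insulin regimen: %.2f U total (%.1f%% basal)\n",
              x$total_U, 100 * x$basal_fraction))
  s <- x$segments
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %s-%s  %.2f U as %d x %.2f U\n",
                s$mode[i], s$start[i], s$end[i],
                s$total_dose_U[i], s$n_events[i], s$event_dose_U[i]))
  }
  invisible(x)
}

#' Expand a regimen into individual infusion events
#'
#' @param regimen A `daily_regimen` from [build_regimen()].
#' @return A data frame with columns `event_index`, `clock_time`, `mode`
#'   and `dose_U`, one row per scheduled infusion event. Basal events are
#'   placed at the end of each interval; bolus events at the segment start.
#' @export
regimen_events <- function(regimen) {
  stopifnot(inherits(regimen, "daily_regimen"))
  s <- regimen$segments
  rows <- list()
  for (i in seq_len(nrow(s))) {
    n <- s$n_events[i]
    if (s$mode[i] == "basal") {
      len <- window_minutes(s$start_min[i], s$end_min[i])
      times <- s$start_min[i] + (len / n) * seq_len(n)
    } else {
      times <- rep(s$start_min[i], n)
    }
    rows[[i]] <- data.frame(
      clock_time = format_clock(times),
      mode = s$mode[i],
      dose_U = rep(s$event_dose_U[i], n)
    )
  }
  out <- do.call(rbind, rows)
  out <- cbind(event_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Worked 27 U regimen preset
#'
#' The shipped worked example: a 75 kg patient with fasting glucose
#' 220 mg/dL needs 27 U/day; three 4 U pre-meal boluses (each delivered as
#' two 2 U events) and three 5-hour basal windows at 0.1 U every 6 minutes
#' (5 U per window, i.e. basal fraction 15/27).
#'
#' @return A `daily_regimen`.
#' @export
table1_regimen <- function() {
  build_regimen(
    total = daily_insulin_requirement(75, 220),
    basal_fraction = 15 / 27,
    bolus_count = 3,
    basal_windows = list(c("6:00", "11:00"), c("13:00", "18:00"),
                         c("20:00", "1:00")),
    basal_interval = 6,
    bolus_windows = list(c("4:00", "6:00"), c("11:00", "13:00"),
                         c("18:00", "20:00")),
    bolus_event_dose = 2
  )
}

#' Write regimen events to CSV
#'
#' @param regimen A `daily_regimen`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regimen_csv <- function(regimen, path) {
  utils::write.csv(regimen_events(regimen), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
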