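# Screw-drive dosing mechanics: dose -> reservoir volume -> plunger travel
# -> screw/motor revolutions -> quadrature encoder pulses, plus the
# dead-volume model behind the minimum effective infusion dose.

#' Pump drive configuration
#'
#' Geometry and transmission constants that turn an insulin dose into plunger
#' travel and encoder feedback pulses. The pulse chain is
#' volume -> axial advance (`4 V / (pi d^2)`) -> screw revolutions (/ pitch)
#' -> motor revolutions (x gear ratio) -> pulses (x encoder lines x
#' quadrature factor).
#'
#' @param stages Drive stages, 1 (single telescoping screw) or 2.
#' @param reservoir_inner_diameter_mm Inner diameter `d` of the reservoir, mm.
#' @param screw_pitch_mm Lead screw pitch `p`, mm per screw revolution.
#' @param gear_ratio Reduction ratio `i` between motor and screw.
#' @param encoder_lines Optical encoder line count `N0`.
#' @param quadrature_factor Edge-decoding multiplier; 1, 2 or 4 (both edges
#'   of both channels).
#' @param insulin_concentration_U_per_ml Drug concentration; U-100 insulin
#'   (the usual rapid-acting formulation) is 100 U/mL, so 0.1 U occupies
#'   1 uL (about 0.001 g of water surrogate).
#' @param dead_volume_ml Lumped dead volume (mL): reservoir and line
#'   elasticity, mechanical backlash and friction losses collapsed into a
#'   single volume that must be taken up before liquid leaves the needle.
#' @param max_stroke_mm Maximum plunger travel.
#' @param name Optional label used in comparison reports.
#' @return An object of class `pump_config`.
#' @seealso [pump_preset()] for the shipped one-/two-stage presets.
#' @export
pump_config <- function(stages,
                        reservoir_inner_diameter_mm,
                        screw_pitch_mm,
                        gear_ratio,
                        encoder_lines,
                        quadrature_factor = 4,
                        insulin_concentration_U_per_ml = 100,
                        dead_volume_ml = 0,
                        max_stroke_mm = 50,
                        name = NULL) {
  if (!stages %in% c(1L, 2L)) stop("`stages` must be 1 or 2", call. = FALSE)
  if (!quadrature_factor %in% c(1L, 2L, 4L)) {
    stop("`quadrature_factor` must be 1, 2 or 4", call. = FALSE)
  }
  geom <- c(reservoir_inner_diameter_mm, screw_pitch_mm, gear_ratio,
            encoder_lines, insulin_concentration_U_per_ml, max_stroke_mm)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("all geometric/transmission fields must be positive", call. = FALSE)
  }
  if (dead_volume_ml < 0) stop("`dead_volume_ml` must be >= 0", call. = FALSE)
  structure(
    list(stages = as.integer(stages),
         reservoir_inner_diameter_mm = reservoir_inner_diameter_mm,
         screw_pitch_mm = screw_pitch_mm,
         gear_ratio = gear_ratio,
         encoder_lines = encoder_lines,
         quadrature_factor = quadrature_factor,
         insulin_concentration_U_per_ml = insulin_concentration_U_per_ml,
         dead_volume_ml = dead_volume_ml,
         max_stroke_mm = max_stroke_mm,
         name = name %||% paste0(stages, "-stage")),
    class = "pump_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pump_config <- function(x, ...) {
  cat(sprintf(
    "Pump drive '%s': %d-stage, d=%.2f mm, pitch=%.2f mm, i=%g, N0=%d x%d\n",
    x$name, x$stages, x$reservoir_inner_diameter_mm, x$screw_pitch_mm,
    x$gear_ratio, x$encoder_lines, x$quadrature_factor))
  cat(sprintf("  %g U/mL, dead volume %.3g uL, max stroke %.1f mm\n",
              x$insulin_concentration_U_per_ml, 1000 * x$dead_volume_ml,
              x$max_stroke_mm))
  cat(sprintf("  resolution: %.4g pulses/U, pulse quantum %.3g U\n",
              encoder_pulses_for_dose(x, 1), pulse_quantum_dose(x)))
  invisible(x)
}

#' Convert an insulin dose to reservoir volume
#'
#' @param dose_U Dose in insulin units; must be non-negative.
#' @param concentration_U_per_ml Concentration (default U-100).
#' @return Volume in mL. At U-100, 0.1 U -> 0.001 mL, i.e. ~0.001 g of the
#'   water surrogate used in gravimetric bench tests.
#' @export
dose_to_volume <- function(dose_U, concentration_U_per_ml = 100) {
  stopifnot(is.numeric(dose_U))
  if (any(dose_U < 0)) stop("`dose_U` must be >= 0", call. = FALSE)
  dose_U / concentration_U_per_ml
}

#' Plunger axial advance for a dose
#'
#' @param config A [pump_config()].
#' @param dose_U Dose in insulin units.
#' @return Axial advance in mm: `4 V / (pi d^2)` with `V` in mm^3.
#' @export
dose_to_advance <- function(config, dose_U) {
  v_mm3 <- 1000 * dose_to_volume(dose_U, config$insulin_concentration_U_per_ml)
  4 * v_mm3 / (pi * config$reservoir_inner_diameter_mm^2)
}

#' Encoder pulses needed for a dose
#'
#' Number of quadrature-decoded encoder pulses the motor shaft must turn
#' through to expel `dose_U`. Exactly linear in dose with zero intercept;
#' returned as a real number — quantisation to whole pulses is the separate
#' explicit [quantize_pulses()].
#'
#' @param config A [pump_config()].
#' @param dose_U Dose in insulin units (>= 0).
#' @return Pulse count (real).
#' @export
encoder_pulses_for_dose <- function(config, dose_U) {
  stopifnot(inherits(config, "pump_config"))
  advance <- dose_to_advance(config, dose_U)
  if (any(advance > config$max_stroke_mm)) {
    stop("dose exceeds the remaining plunger stroke (", config$max_stroke_mm,
         " mm)", call. = FALSE)
  }
  screw_rev <- advance / config$screw_pitch_mm
  screw_rev * config$gear_ratio * config$encoder_lines *
    config$quadrature_factor
}

#' Quantise a fractional pulse count to whole pulses
#'
#' @param pulses Real pulse count from [encoder_pulses_for_dose()].
#' @return `floor(pulses)` as integer-valued numeric.
#' @export
quantize_pulses <- function(pulses) floor(pulses)

#' Volume and dose moved by a single encoder pulse
#'
#' @param config A [pump_config()].
#' @return `pulse_quantum_volume()`: mL per pulse; `pulse_quantum_dose()`:
#'   U per pulse.
#' @export
pulse_quantum_volume <- function(config) {
  # invert the pulse chain for one pulse
  rev_per_pulse <- 1 / (config$encoder_lines * config$quadrature_factor *
                          config$gear_ratio)
  advance <- rev_per_pulse * config$screw_pitch_mm
  advance * pi * config$reservoir_inner_diameter_mm^2 / 4 / 1000
}

#' @rdname pulse_quantum_volume
#' @export
pulse_quantum_dose <- function(config) {
  pulse_quantum_volume(config) * config$insulin_concentration_U_per_ml
}

#' Minimum effective infusion dose
#'
#' The smallest commanded dose that produces measurable liquid output: its
#' volume must cover the drive's lumped dead volume plus at least one
#' pulse-quantum of volume. Monotone non-decreasing in dead volume and
#' non-increasing as pulse resolution rises.
#'
#' @param config A [pump_config()].
#' @return Dose in insulin units.
#' @export
min_effective_dose <- function(config) {
  stopifnot(inherits(config, "pump_config"))
  (config$dead_volume_ml + pulse_quantum_volume(config)) *
    config$insulin_concentration_U_per_ml
}

#' Shipped pump drive presets
#'
#' Two calibration-fixture drive configurations representing the single- and
#' two-stage telescoping screw variants of a plunger pump. The geometry is
#' plausible for a palm-sized pump; the dead-volume constants are calibrated
#' in closed form so the minimum effective doses equal the bench-measured
#' 0.095 U (one-stage) and 0.047 U (two-stage) reference values — they are
#' fixtures, not measurements.
#'
#' @param which `"one_stage"` or `"two_stage"`.
#' @return A [pump_config()].
#' @export
pump_preset <- function(which = c("one_stage", "two_stage")) {
  which <- match.arg(which)
  if (which == "one_stage") {
    cfg <- pump_config(stages = 1, reservoir_inner_diameter_mm = 9.5,
                       screw_pitch_mm = 1.0, gear_ratio = 25,
                       encoder_lines = 16, quadrature_factor = 4,
                       max_stroke_mm = 45, name = "one_stage")
    target <- 0.095
  } else {
    cfg <- pump_config(stages = 2, reservoir_inner_diameter_mm = 8.0,
                       screw_pitch_mm = 0.5, gear_ratio = 100,
                       encoder_lines = 16, quadrature_factor = 4,
                       max_stroke_mm = 75, name = "two_stage")
    target <- 0.047
  }
  # calibrate the lumped dead volume to the reference minimum effective dose
  cfg$dead_volume_ml <- target / cfg$insulin_concentration_U_per_ml -
    pulse_quantum_volume(cfg)
  cfg
}

#' Compare two drive configurations at a dose
#'
#' @param c1,c2 [pump_config()] objects.
#' @param dose_U Dose at which to compare pulse counts (default 0.05 U, the
#'   resolution target for precise delivery).
#' @return A list of class `pump_comparison`: a `table` data frame (one row
#'   per config with pulses, pulse-quantum dose and minimum effective dose)
#'   plus `finer` (name of the config with more pulses per unit dose, or
#'   `"tie"`) and `min_dose_reduction_pct`, the relative reduction in
#'   minimum effective dose going from `c1` to `c2`, in percent.
#' @export
compare_stage_configs <- function(c1, c2, dose_U = 0.05) {
  stopifnot(inherits(c1, "pump_config"), inherits(c2, "pump_config"))
  tab <- data.frame(
    config_name = c(c1$name, c2$name),
    dose_U = dose_U,
    pulses = c(encoder_pulses_for_dose(c1, dose_U),
               encoder_pulses_for_dose(c2, dose_U)),
    pulse_quantum_U = c(pulse_quantum_dose(c1), pulse_quantum_dose(c2)),
    min_effective_dose_U = c(min_effective_dose(c1), min_effective_dose(c2))
  )
  finer <- if (isTRUE(all.equal(tab$pulses[1], tab$pulses[2]))) {
    "tie"
  } else {
    tab$config_name[which.max(tab$pulses)]
  }
  structure(
    list(table = tab, finer = finer,
         min_dose_reduction_pct =
           100 * (tab$min_effective_dose_U[1] - tab$min_effective_dose_U[2]) /
           tab$min_effective_dose_U[1]),
    class = "pump_comparison"
  )
}

#' @export
print.pump_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("finer: %s; min-dose reduction %.2f%%\n",
              x$finer, x$min_dose_reduction_pct))
  invisible(x)
}

#' Write a drive comparison report to CSV
#'
#' @param comparison A `pump_comparison` from [compare_stage_configs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
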