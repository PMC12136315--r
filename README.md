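# pumptwin

A desk-scale digital twin of a plunger-driven insulin pump, for engineers
and researchers studying infusion accuracy. The package models the whole
delivery chain — prescription arithmetic, screw-drive mechanics, the motor
speed loop, deviation statistics, and learned error compensation — so that
design questions (how much does a two-stage screw buy? does adaptive gain
scheduling help under load steps? how much residual error can feed-forward
compensation remove?) can be answered quantitatively without a gravimetric
bench.

## What it computes

* **Dose regimen** — total daily insulin from body weight and fasting
  glucose, `U = 6K(P−100)/2000` (units; `K` kg, `P` mg/dL), and exact
  basal/bolus schedules with midnight-wrapping windows.
* **Drive mechanics** — dose → volume → plunger advance `4V/(πd²)` → screw
  and motor revolutions → quadrature encoder pulses; pulse quanta, stroke
  limits, and the minimum effective dose set by lumped dead volume.
  Shipped one-/two-stage presets are calibrated to the bench reference
  minimum doses of 0.095 U and 0.047 U.
* **Speed loop** — a first-order BLDCM speed/voltage lag discretised
  exactly (ZOH), driven by an incremental PID or by a BP-neural-network
  adaptive PID whose three gains are emitted each millisecond by an online
  trained 4–5–3 perceptron; load-step experiments and step-response
  metrics (overshoot, ±2% settling, disturbance recovery).
* **Deviation statistics** — single/mean/max infusion deviation
  `|D_t − D_a|/D_t × 100`, cumulative basal-rate deviation against
  `rate × t`, and paired t-tests (raw data or summary statistics).
* **Compensation** — an LSTM stack (hand-implemented, full BPTT) forecasts
  the cumulative deviation one step ahead; the forecast for the final
  planned infusion is spread uniformly across all commands. Grid search
  over epochs × batch × hidden units ranks models by test MAPE/RMSE.
* **Synthetic bench data** — seeded generators with under-delivery bias,
  drift and weighing noise, plus verbatim fixtures of the published bench
  tables for regression tests.

## Worked example

```r
library(pumptwin)

# 75 kg patient, fasting glucose 220 mg/dL
daily_insulin_requirement(75, 220)
#> [1] 27

table1_regimen()
#> Daily insulin regimen: 27.00 U total (55.6% basal)
#>   bolus 04:00-06:00  4.00 U as 2 x 2.00 U
#>   bolus 11:00-13:00  4.00 U as 2 x 2.00 U
#>   bolus 18:00-20:00  4.00 U as 2 x 2.00 U
#>   basal 06:00-11:00  5.00 U as 50 x 0.10 U
#>   basal 13:00-18:00  5.00 U as 50 x 0.10 U
#>   basal 20:00-01:00  5.00 U as 50 x 0.10 U

# one- vs two-stage screw drive at the 0.05 U resolution target
compare_stage_configs(pump_preset("one_stage"), pump_preset("two_stage"))
#>  config_name dose_U    pulses pulse_quantum_U min_effective_dose_U
#>    one_stage   0.05  11.28633    0.0044301365                0.095
#>    two_stage   0.05 127.32395    0.0003926991                0.047
#> finer: two_stage; min-dose reduction 50.53%
```

The two-stage drive produces ~11× more encoder pulses per dose and halves
the minimum effective dose — the mechanical argument for the telescoping
screw. On the control side:

```r
cmp <- compare_controllers(seed = 1)
cmp$pid_metrics
#> overshoot 3.43%, settling 0.08 s, recovery 0 s, ss error 4.37e-09 rpm
cmp$bp_metrics
#> overshoot 0.00%, settling 0.063 s, recovery 0 s, ss error 0 rpm
```

The adaptive controller removes the fixed tuning's 3.4% overshoot and
settles faster under the 1 → 1.5 N·m load step. Finally, compensation:

```r
gen <- generator_spec(n_infusions = 120, commanded_dose_U = 2,
                      bias_fraction = 0.035, noise_sd_U = 0.02, seed = 1)
log <- generate_infusions(gen)
series <- deviation_series(log)
fit <- fit_deviation_model(series, model_spec(seed = 2, epochs = 150))
fit
#> Deviation model LDL (32 units): test MAPE 0.18%, RMSE 0.0185 U (n=120, 102/18 split)
make_plan(predicted_total_deviation(fit, series), 120)
#> Compensation plan: 8.1491 U total over 120 infusions (0.06791 U each)
```

Against a true per-infusion bias of 0.070 U the plan recovers 0.068 U;
applying it cuts the mean infusion deviation from ~3.4% to under 1% in the
re-simulated delivery.

A shell entry point wraps the same functions
(`Rscript inst/cli/pumptwin.R dose-plan --weight 75 --glucose 220`); see
`?pump_cli` for the command set.

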