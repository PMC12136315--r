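# Shared fixtures built in code.

# infusion log for one commanded dose of the published single-dose table
table2_log <- function(dose_U) {
  t2 <- table_fixture("table2")
  rows <- t2[t2$set_dose_U == dose_U, ]
  infusion_log(rep(dose_U, nrow(rows)), rows$actual_dose_U)
}

# small, quick model spec for LSTM unit tests
quick_spec <- function(hidden_units = 6, epochs = 40, batch_size = 64,
                       window_length = 10, ...) {
  model_spec(hidden_units = hidden_units, epochs = epochs,
             batch_size = batch_size, window_length = window_length, ...)
}

# standard synthetic under-delivery scenario (2 U infusions, 3.5% bias)
synth_spec <- function(seed = 1L, ...) {
  generator_spec(n_infusions = 120, commanded_dose_U = 2,
                 bias_fraction = 0.035, drift_per_infusion_U = 0,
                 noise_sd_U = 0.02, seed = seed, ...)
}
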