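test_that("MAPE and RMSE follow their definitions", {
  expect_equal(mape(c(2, 4), c(2, 4)), 0)
  expect_equal(mape(c(2, 4), c(1, 5)), 37.5)
  a <- runif(10, 1, 5)
  expect_equal(mape(a, 1.1 * a), 10, tolerance = 1e-9)
  expect_error(mape(c(0, 0), c(1, 1)), "undefined")
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(c(1, 1), c(2, 0)), 1)  # residuals all +/- c
})

test_that("deviation series keeps an exact prefix sum", {
  set.seed(2)
  dev <- rnorm(50, 0.07, 0.02)
  ser <- deviation_series(dev, commanded_dose_U = 2)
  expect_equal(ser$cumulative_deviation_U, cumsum(dev))
  log <- generate_infusions(synth_spec())
  ser2 <- deviation_series(log)
  expect_equal(ser2$cumulative_deviation_U,
               cumsum(log$commanded_dose_U - log$delivered_dose_U))
})

test_that("chronological split partitions the series in order", {
  ser <- deviation_series(seq_len(120) * 0.1, commanded_dose_U = 2)
  sp <- chronological_split(ser, 0.85)
  expect_length(sp$train, 102)
  expect_length(sp$test, 18)
  expect_equal(c(sp$train, sp$test), ser$cumulative_deviation_U)
  # other published fractions
  expect_length(chronological_split(ser, 0.75)$train, 90)
  expect_length(chronological_split(ser, 0.90)$train, 108)
  # fraction at the edge leaves no usable test split
  expect_error(chronological_split(ser, 0.999, window_length = 10),
               "too short")
  expect_error(chronological_split(ser, 1), "strictly between")
})

test_that("model fitting is deterministic under a fixed seed", {
  ser <- deviation_series(generate_infusions(synth_spec(seed = 3)))
  f1 <- fit_deviation_model(ser, quick_spec(seed = 5))
  f2 <- fit_deviation_model(ser, quick_spec(seed = 5))
  expect_identical(f1$stack, f2$stack)
  expect_identical(f1$mape, f2$mape)
  expect_identical(f1$train_curve, f2$train_curve)
  f3 <- fit_deviation_model(ser, quick_spec(seed = 6))
  expect_false(identical(f1$mape, f3$mape))
})

test_that("a constant cumulative series is learned almost exactly", {
  # one initial offset then zero further deviation: constant target
  ser <- deviation_series(c(0.5, rep(0, 119)), commanded_dose_U = 2)
  fit <- fit_deviation_model(ser, quick_spec(seed = 3, epochs = 100))
  expect_lt(fit$mape, 1)
})

test_that("zero training epochs still yields finite metrics", {
  ser <- deviation_series(generate_infusions(synth_spec(seed = 4)))
  fit <- fit_deviation_model(ser, quick_spec(seed = 1, epochs = 0))
  expect_true(is.finite(fit$mape))
  expect_true(is.finite(fit$rmse))
  expect_length(fit$train_curve, 0)
})

test_that("learning curves have one entry per epoch and smoothed train loss
          does not increase", {
  ser <- deviation_series(generate_infusions(synth_spec(seed = 1)))
  fit <- fit_deviation_model(ser, quick_spec(seed = 2, epochs = 60))
  expect_length(fit$train_curve, 60)
  expect_length(fit$test_curve, 60)
  expect_length(fit$train_accuracy, 60)
  sm <- as.numeric(stats::filter(fit$train_curve, rep(1 / 10, 10),
                                 sides = 1))
  sm <- sm[!is.na(sm)]
  rel_inc <- diff(sm) / sm[-length(sm)]
  expect_lt(max(rel_inc), 0.02)
  # accuracy bounded in [0, 1]
  expect_true(all(fit$test_accuracy >= 0 & fit$test_accuracy <= 1))
})

test_that("alternative layer patterns train", {
  ser <- deviation_series(generate_infusions(synth_spec(seed = 9)))
  for (pat in c("LLD", "LDDL")) {
    fit <- fit_deviation_model(ser, quick_spec(seed = 1, epochs = 15,
                                               layer_pattern = pat))
    expect_true(is.finite(fit$mape))
  }
  expect_error(
    fit_deviation_model(deviation_series(rep(0.1, 120),
                                         commanded_dose_U = 2),
                        model_spec(layer_pattern = "XX")),
    "3-4 characters")
})

test_that("grid search ranks by MAPE with deterministic tie-breaks", {
  ser <- deviation_series(generate_infusions(synth_spec(seed = 3)))
  g <- grid_search(ser, epochs = c(15, 30), batch_sizes = 64,
                   hidden_units = c(4, 6),
                   base_spec = quick_spec(seed = 2))
  expect_equal(nrow(g), 4)
  expect_false(is.unsorted(g$mape))
  expect_equal(g$rank, 1:4)
  # single-cell grid trivially wins
  g1 <- grid_search(ser, epochs = 15, batch_sizes = 64, hidden_units = 4,
                    base_spec = quick_spec(seed = 2))
  expect_equal(nrow(g1), 1)
  expect_equal(g1$rank, 1L)
})

test_that("one-step predictions cover every window and the final index", {
  ser <- deviation_series(generate_infusions(synth_spec(seed = 6)))
  fit <- fit_deviation_model(ser, quick_spec(seed = 1, epochs = 30))
  pr <- predict_deviation(fit, ser)
  expect_equal(pr$index, 11:120)
  expect_equal(predicted_total_deviation(fit, ser),
               pr$predicted_cumulative_U[nrow(pr)])
})

test_that("compensation plans conserve the predicted total exactly", {
  plan <- make_plan(12, 120)
  expect_equal(plan$per_infusion_compensation_U, 0.1)
  expect_equal(plan$per_infusion_compensation_U * plan$n_infusions,
               plan$predicted_total_deviation_U)
  expect_equal(make_plan(0, 7)$per_infusion_compensation_U, 0)
  expect_error(make_plan(1, 0), ">= 1")
})

test_that("applying a plan inflates commands and checks the count", {
  log <- generate_infusions(synth_spec(seed = 2))
  plan <- make_plan(8.4, 120)
  out <- apply_plan(log, plan)
  expect_equal(out$commanded_dose_U, log$commanded_dose_U + 0.07)
  expect_equal(out$delivered_dose_U, log$delivered_dose_U)
  # zero plan is the identity
  expect_equal(apply_plan(log, make_plan(0, 120)), log)
  expect_error(apply_plan(log, make_plan(1, 60)), "covers 60")
})

test_that("compensating by the true bias cancels the systematic deviation", {
  spec <- synth_spec(seed = 31)
  log <- generate_infusions(spec)
  bias_U <- 2 * 0.035
  comp <- apply_plan(log, make_plan(bias_U * 120, 120))
  redelivery <- simulate_delivery(comp$commanded_dose_U,
                                  synth_spec(seed = 32))
  resid <- mean(2 - redelivery$delivered_dose_U)
  # second-order residual: the add-on itself is under-delivered by the bias
  expect_lt(abs(resid - bias_U * 0.035), 3 * 0.02 / sqrt(120))
  # and the compensated log beats the uncompensated one
  dev_comp <- mean(abs(2 - redelivery$delivered_dose_U) / 2 * 100)
  expect_lt(dev_comp, deviation_report(log)$mean_deviation_pct)
})

test_that("series CSV round-trips through both schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  ser <- deviation_series(generate_infusions(synth_spec(seed = 12)))
  write_series_csv(ser, path)
  back <- read_series_csv(path)
  expect_equal(back$per_infusion_deviation_U, ser$per_infusion_deviation_U,
               tolerance = 1e-9)
  expect_equal(back$cumulative_deviation_U, ser$cumulative_deviation_U,
               tolerance = 1e-9)
})
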