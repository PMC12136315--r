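test_that("single deviation follows the absolute-percent rule", {
  expect_equal(single_deviation(1.00, 0.96), 4.00)
  expect_equal(single_deviation(2.00, 2.00), 0)
  expect_equal(single_deviation(10.00, 10.31), 3.10, tolerance = 1e-9)
  # signed variant keeps the over-delivery sign
  expect_equal(single_deviation(10.00, 10.31, signed = TRUE), -3.10,
               tolerance = 1e-9)
  expect_error(single_deviation(0, 1), "positive")
})

test_that("deviation is invariant to a common dose scale", {
  set.seed(5)
  for (i in 1:25) {
    theo <- runif(1, 0.1, 10)
    act <- theo * runif(1, 0.9, 1.1)
    c_ <- runif(1, 0.01, 100)
    expect_equal(single_deviation(c_ * theo, c_ * act),
                 single_deviation(theo, act), tolerance = 1e-9)
  }
})

test_that("mean deviation is the arithmetic mean", {
  expect_equal(mean_deviation(rep(2.5, 7)), 2.5)
  expect_error(mean_deviation(numeric(0)), "non-empty")
})

test_that("published single-dose rows reproduce their printed statistics", {
  rep1 <- deviation_report(table2_log(1))
  expect_equal(rep1$max_deviation_pct, 4.00, tolerance = 0.005)
  expect_equal(rep1$mean_deviation_pct, 3.30, tolerance = 0.005)
  rep5 <- deviation_report(table2_log(5))
  expect_equal(rep5$max_deviation_pct, 4.40, tolerance = 0.005)
  expect_equal(rep5$mean_deviation_pct, 2.46, tolerance = 0.005)
  rep10 <- deviation_report(table2_log(10))
  expect_equal(rep10$max_deviation_pct, 3.90, tolerance = 0.005)
  expect_equal(rep10$mean_deviation_pct, 3.14, tolerance = 0.005)
})

test_that("deviation report equals a brute-force oracle on random logs", {
  set.seed(17)
  n <- 1000
  cmd <- runif(n, 0.1, 10)
  del <- pmax(cmd * (1 + rnorm(n, -0.03, 0.03)), 0)
  log <- infusion_log(cmd, del)
  rep <- deviation_report(log)
  # independent loop over the defining formula
  devs <- numeric(n)
  for (i in seq_len(n)) devs[i] <- abs(cmd[i] - del[i]) / cmd[i] * 100
  expect_equal(rep$per_record_deviation_pct, devs, tolerance = 1e-12)
  expect_equal(rep$max_deviation_pct, max(devs), tolerance = 1e-12)
  expect_equal(rep$min_deviation_pct, min(devs), tolerance = 1e-12)
  expect_equal(rep$mean_deviation_pct, sum(devs) / n, tolerance = 1e-12)
  # single record: max = min = mean
  r1 <- deviation_report(infusion_log(2, 1.9))
  expect_equal(r1$max_deviation_pct, r1$mean_deviation_pct)
  expect_equal(r1$min_deviation_pct, r1$mean_deviation_pct)
})

test_that("basal-rate accounting reproduces the published reads", {
  expect_equal(basal_run_report(0.5, 6, 2.87)$total_deviation_pct, 4.33,
               tolerance = 0.005)
  expect_equal(basal_run_report(0.5, 22, 10.71)$total_deviation_pct, 2.64,
               tolerance = 0.005)
  # perfect delivery scores zero everywhere
  t_ <- c(1, 2, 5, 10)
  perfect <- basal_run_report(0.5, t_, 0.5 * t_)
  expect_equal(perfect$total_deviation_pct, rep(0, 4))
})

test_that("basal deviation at a read depends only on rate*t and the reading", {
  r1 <- basal_run_report(0.5, c(2, 6), c(0.9, 2.87))
  r2 <- basal_run_report(1.0, 3, 2.87)  # same rate*t = 3 U at the 6 h read
  expect_equal(r1$total_deviation_pct[2], r2$total_deviation_pct[1])
})

test_that("basal report rejects bad inputs", {
  expect_error(basal_run_report(0.5, c(2, 1), c(1, 2)), "increasing")
  expect_error(basal_run_report(0.5, c(1, 2), c(2, 1)), "non-decreasing")
})

test_that("paired t-test matches stats::t.test as an independent oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    a <- rnorm(n, 5, 1)
    b <- rnorm(n, 4.8, 1)
    mine <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(c(mine$ci95_low, mine$ci95_high),
                 unname(as.vector(ref$conf.int)), tolerance = 1e-10)
    expect_equal(mine$degrees_of_freedom, n - 1)
  }
})

test_that("paired t-test is antisymmetric in its arguments", {
  a <- c(5.78, 5.14, 4.39, 4.58, 4.45)
  b <- c(5.67, 4.78, 4.34, 4.52, 4.35)
  ab <- paired_t_test(a, b)
  ba <- paired_t_test(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$ci95_high - ab$ci95_low, ba$ci95_high - ba$ci95_low)
})

test_that("degenerate paired t-tests hit their sentinels", {
  a <- c(1, 2, 3)
  expect_equal(paired_t_test(a, a)$t_statistic, 0)
  expect_equal(paired_t_test(a, a)$p_value, 1)
  # zero variance, non-zero mean difference
  r <- paired_t_test(a + 1, a)
  expect_equal(r$t_statistic, Inf)
  expect_equal(r$p_value, 0)
})

test_that("summary-driven t-test matches the published worked example", {
  r <- t_test_from_summary(10, 0.35300, 0.35923)
  expect_lt(abs(r$se_mean - 0.11360), 5e-6)
  expect_lt(abs(r$t_statistic - 3.107), 1e-3)
  expect_equal(r$degrees_of_freedom, 9)
  expect_lt(abs(r$ci95_low - 0.09602), 1e-4)
  expect_lt(abs(r$ci95_high - 0.60998), 1e-4)
  expect_lt(abs(r$p_value - 0.013), 1e-3)
  # textbook quantile anchor: t = 2.262 at df 9 is p = 0.05
  expect_equal(t_test_from_summary(10, 2.262, sqrt(10))$p_value, 0.05,
               tolerance = 1e-3)
  expect_equal(t_test_from_summary(10, 0, 1)$t_statistic, 0)
  expect_equal(t_test_from_summary(4, 1, 1)$t_statistic, 2)
})

test_that("infusion CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  log <- infusion_log(rep(2, 5), c(1.9, 1.95, 1.92, 1.93, 1.94))
  write_infusion_csv(log, path)
  back <- read_infusion_csv(path)
  expect_equal(back$delivered_dose_U, log$delivered_dose_U)
  expect_equal(back$commanded_dose_U, log$commanded_dose_U)
})
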