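test_that("plant discretisation matches the continuous first-order response", {
  m <- plant_model(gain = 1, time_constant = 0.05, sample_time = 0.001,
                   load_gain = 0)
  # equilibrium
  expect_equal(plant_step(m, 0, 0, 0), 0)
  # analytic step response at every sample point, to 1e-9
  y <- 0
  for (k in 1:400) {
    y <- plant_step(m, y, 1, 0)
    expect_equal(y, 1 - exp(-k * 0.001 / 0.05), tolerance = 1e-9)
  }
  # final value theorem: y -> gain*u after ~7 time constants
  expect_equal(y, 1, tolerance = 1e-3)
})

test_that("incremental PID obeys its forced arithmetic", {
  s <- pid_state(kp = 0, ki = 0, u_min = -10, u_max = 10)
  s <- pid_step(s, 100, 50)
  expect_equal(s$u, 0)  # all gains zero: output unchanged
  s2 <- pid_state(kp = 1, ki = 0, u_min = -100, u_max = 100)
  s2 <- pid_step(s2, 5, 0)  # first call, e = 5, e_prev = 0
  expect_equal(s2$u, 5)
  # clamping
  s3 <- pid_state(kp = 10, ki = 0, u_min = 0, u_max = 1)
  s3 <- pid_step(s3, 100, 0)
  expect_equal(s3$u, 1)
})

test_that("P-only closed loop settles at its closed-form steady state", {
  m <- plant_model(gain = 100, load_gain = 0)
  kp <- 0.01
  tr <- run_experiment(m, "pid", setpoint = 2000,
                       loads = load_schedule(0, 0),
                       duration = 1, pid = pid_state(kp = kp, ki = 0))
  expected <- kp * 100 / (1 + kp * 100) * 2000
  expect_equal(tail(tr$speed_rpm, 1), expected, tolerance = 0.005 * expected)
})

test_that("integral action removes steady-state error", {
  m <- plant_model()
  tr <- run_experiment(m, "pid", 2000, load_schedule(0, 1), duration = 0.6,
                       pid = pid_state(kp = 0.03, ki = 0.01))
  # < 0.1% after >10 time constants
  expect_lt(abs(tail(tr$speed_rpm, 1) - 2000), 0.001 * 2000)
})

test_that("zero-gain controller leaves the plant at the load equilibrium", {
  m <- plant_model()
  tr <- run_experiment(m, "pid", 2000, load_schedule(0, 0), duration = 0.2,
                       pid = pid_state(kp = 0, ki = 0))
  expect_true(all(tr$speed_rpm == 0))
})

test_that("BP-PID with zero learning rate is bit-identical to fixed PID", {
  m <- plant_model()
  loads <- load_schedule()
  net0 <- bp_network(learning_rate = 0, seed = 4)
  tr_bp <- run_experiment(m, "bp_pid", 2000, loads, 1,
                          pid = pid_state(0, 0), net = net0)
  expect_equal(length(unique(tr_bp$kp)), 1L)
  tr_fx <- run_experiment(m, "pid", 2000, loads, 1,
                          pid = pid_state(kp = tr_bp$kp[1], ki = tr_bp$ki[1],
                                          kd = tr_bp$kd[1]))
  expect_identical(tr_bp$speed_rpm, tr_fx$speed_rpm)
})

test_that("BP-PID emitted gains respect their ceilings", {
  net <- bp_network(kp_max = 0.5, ki_max = 0.05, kd_max = 0, seed = 2)
  # all-zero output weights force gains at half ceiling
  net0 <- net
  net0$w_ho <- net0$w_ho * 0
  res <- bp_pid_step(net0, pid_state(0, 0), 2000, 0, jac_sign = 0)
  expect_equal(unname(res$gains), c(0.25, 0.025, 0))
  tr <- run_experiment(plant_model(), "bp_pid", 2000, load_schedule(), 1,
                       pid = pid_state(0, 0), net = net)
  expect_true(all(tr$kp >= 0 & tr$kp <= 0.5))
  expect_true(all(tr$ki >= 0 & tr$ki <= 0.05))
  expect_true(all(tr$kd == 0))
  expect_true(all(is.finite(tr$speed_rpm)))
})

test_that("step metrics follow their definitions", {
  # trace peaking at 1.2x setpoint has 20% overshoot
  tr <- data.frame(time_s = seq(0, 1, by = 0.01),
                   speed_rpm = c(seq(0, 1200, length.out = 50),
                                 seq(1190, 1000, length.out = 51)))
  m <- step_metrics(tr, 1000)
  expect_equal(m$overshoot_pct, 20)
  # monotone trace converging below setpoint: overshoot zero
  tr2 <- data.frame(time_s = seq(0, 1, by = 0.001))
  tr2$speed_rpm <- 990 * (1 - exp(-tr2$time_s / 0.05))
  m2 <- step_metrics(tr2, 1000)
  expect_equal(m2$overshoot_pct, 0)
  # analytic first-order closed loop: settling at -T*log(0.02)
  tcl <- 0.05
  tr3 <- data.frame(time_s = seq(0, 1, by = 0.001))
  tr3$speed_rpm <- 1000 * (1 - exp(-tr3$time_s / tcl))
  m3 <- step_metrics(tr3, 1000)
  # agreement within one sample of the trace
  expect_lt(abs(m3$settling_time_s - (-tcl * log(0.02))), 0.0011)
  # a trace that never settles reports an infinite sentinel
  tr4 <- data.frame(time_s = seq(0, 1, by = 0.01),
                    speed_rpm = rep(c(500, 1500), 51)[1:101])
  expect_equal(step_metrics(tr4, 1000)$settling_time_s, Inf)
})

test_that("load schedule evaluates stepwise", {
  sch <- load_schedule(c(0, 0.5), c(1, 1.5))
  expect_equal(load_at(sch, c(0, 0.25, 0.5, 0.75)), c(1, 1, 1.5, 1.5))
  expect_error(load_schedule(c(0.1, 0.5), c(1, 2)), "start at 0")
  expect_error(load_schedule(c(0, 0), c(1, 2)), "strictly")
})

test_that("default load-step comparison favours the adaptive controller", {
  cmp <- compare_controllers(seed = 1L)
  expect_lte(cmp$bp_metrics$overshoot_pct, cmp$pid_metrics$overshoot_pct)
  expect_lte(cmp$bp_metrics$disturbance_recovery_time_s,
             cmp$pid_metrics$disturbance_recovery_time_s)
  # the fixed tuning genuinely overshoots, so the comparison is informative
  expect_gt(cmp$pid_metrics$overshoot_pct, 1)
  # both reject the load step and hold the setpoint
  expect_lt(abs(cmp$bp_metrics$steady_state_error_rpm), 2)
  expect_lt(abs(cmp$pid_metrics$steady_state_error_rpm), 2)
})

test_that("trace export writes the full column set", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- run_experiment(plant_model(), "pid", 2000, load_schedule(0, 1), 0.05,
                       pid = pid_state(0.03, 0.01))
  write_trace_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_s", "setpoint_rpm", "speed_rpm", "u_V", "load_Nm",
                     "kp", "ki", "kd"))
})
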