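test_that("drive shifts move both thresholds equally; the gap needs MA inhibition", {
  sw <- pr_switch_human()
  p2 <- pr_switch_to_two_process(sw)
  sw2 <- sw; sw2$D0_v <- sw$D0_v + 1.7
  p2b <- pr_switch_to_two_process(sw2)
  expect_equal(p2b$H0_plus - p2$H0_plus, -1.7 / sw$nu_vh)
  expect_equal(p2b$H0_minus - p2$H0_minus, -1.7 / sw$nu_vh)
  expect_equal(p2b$H0_plus - p2b$H0_minus, p2$H0_plus - p2$H0_minus)
  # the threshold gap is the VLPO inhibition by the MA during wake
  expect_equal(p2$H0_plus - p2$H0_minus, sw$nu_vm * sw$Q_bar / sw$nu_vh)
  # without it the mapping degenerates and is rejected
  sw3 <- sw; sw3$nu_vm <- 0
  expect_error(pr_switch_to_two_process(sw3), "H0_minus")
})

test_that("switch model and mapped two-process model have matching transitions", {
  sw <- pr_switch_human()
  p2 <- pr_switch_to_two_process(sw)
  sim_sw <- simulate_pr(sw, t_span = 24 * 10, init = "sleep")
  ev <- sim_sw$pattern$events
  t0 <- ev$time_h[ev$transition == "wake_to_sleep"][1L]
  H0 <- sim_sw$timeseries$H[which.min(abs(sim_sw$timeseries$time_h - t0))]
  sim_2p <- simulate_two_process(p2, t_span = 24 * 10 - t0, H_init = H0,
                                 state_init = "sleep", t_start = t0)
  m <- sleepdyn:::match_transitions(sim_sw$pattern, sim_2p$pattern, max_lag = 2)
  m <- m[m$time_a > t0, , drop = FALSE]
  expect_gte(nrow(m), 16L)
  # the slow-manifold equivalence is exact; the residual is the fast
  # relaxation of the potentials through the switch (tens of seconds)
  expect_lt(max(abs(m$diff_h)), 2 / 60)
})

test_that("calibration returns a mean-wake-rate switch and matched extrema", {
  cal <- sleepdyn:::human_calibration()
  sw <- cal$switch
  p <- pr_human()
  expect_lt(sw$Q_bar, 0.1 * p$Q_max)         # far below the maximum rate
  sim <- human_pr_sim()
  ts <- sim$timeseries[sim$timeseries$time_h > 48, ]
  mean_wake_Q <- mean(ts$Q_m[ts$state == "wake"])
  expect_lt(abs(sw$Q_bar - mean_wake_Q) / mean_wake_Q, 0.05)
  expect_equal(sw$V_th, cal$fold_drives[["D_v_minus"]])
  # the mapped wake-phase exponential passes through both homeostat extrema
  p2 <- cal$two_process
  ex <- cal$extrema
  H_at_max <- sleepdyn:::h_wake(ex$t_max, ex$t_min, ex$H_min, p2)
  expect_equal(H_at_max, ex$H_max, tolerance = 1e-9)
  # and the mapped model's own sleep onset falls within minutes of the
  # source model's homeostat maximum
  sim2 <- simulate_two_process(p2, t_span = 48, H_init = ex$H_min,
                               state_init = "wake", t_start = ex$t_min)
  on1 <- sim2$pattern$events$time_h[1L]
  expect_lt(abs(on1 - ex$t_max), 10 / 60)
})

test_that("calibrating the switch model itself recovers its own parameters", {
  sw <- pr_switch_human()
  cal2 <- calibrate_switch_from_pr(sw, report = FALSE)
  expect_equal(cal2$switch$V_th, sw$V_th, tolerance = 1e-10)
  expect_equal(cal2$switch$Q_bar, sw$Q_bar, tolerance = 1e-2)
  expect_equal(cal2$switch$nu_vm, sw$nu_vm, tolerance = 1e-2)
})

test_that("full sigmoid model and mapped two-process model agree over ten days", {
  cal <- cached("human_cal_report",
                calibrate_switch_from_pr(pr_human(), report = TRUE,
                                         compare_days = 10))
  rep <- cal$report
  expect_gte(nrow(rep$transitions), 18L)
  # agreement within the saddle-node ghost-passage lag of the firing-rate
  # threshold label (a systematic few-minutes offset)
  expect_lt(rep$max_abs_diff_h, 0.25)
  expect_lt(max(abs(rep$extrema_diff)), 0.25)
})

test_that("calibration refuses a non-monophasic source", {
  p <- pr_human(chi = 10)   # polyphasic regime
  expect_error(calibrate_switch_from_pr(p, report = FALSE), "monophasic")
})
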