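test_that("frozen drives inside the bistable band preserve the initial state", {
  # freeze the drives by removing both the circadian and homeostatic inputs
  # and placing the constant VLPO drive mid-band
  p <- pr_human(nu_vh = 0, D0_v = 1.9, circadian = circadian_waveform(0))
  wake <- simulate_pr(p, t_span = 3, init = "wake", dt_out = 0.002)
  expect_true(all(wake$timeseries$Q_m[wake$timeseries$time_h > 0.2] > 1))
  sleep <- simulate_pr(p, t_span = 3, init = "sleep", dt_out = 0.002)
  expect_true(all(sleep$timeseries$Q_m[sleep$timeseries$time_h > 0.2] < 1))
  # both are frozen-drive equilibria of the slow manifold
  sols <- slow_manifold_solve(pr_human(), D_v = 1.9)
  expect_equal(nrow(sols), 3L)
})

test_that("the canonical human set produces a converged monophasic cycle", {
  sim <- human_pr_sim()
  s <- classify_pattern(sim$pattern)
  expect_true(s$converged)
  expect_equal(s$period_days, 1)
  expect_equal(s$episodes_per_day, 1)
  expect_gt(s$daily_sleep_h, 7); expect_lt(s$daily_sleep_h, 10)
})

test_that("perturbed potentials relax to the slow manifold within minutes", {
  p <- pr_human()
  sim <- human_pr_sim()
  # sample the middle of the last full wake episode, far from transitions
  ev <- sim$pattern$events
  w_on <- max(ev$time_h[ev$transition == "sleep_to_wake"])
  t_mid <- w_on + 6
  mid <- sim$timeseries[which.min(abs(sim$timeseries$time_h - t_mid)), ]
  pert <- simulate_pr(p, t_span = 1,
                      init = c(mid$V_v + 3, mid$V_m - 2, mid$H),
                      t_start = mid$time_h, dt_out = 0.002)
  after <- pert$timeseries[pert$timeseries$time_h > mid$time_h + 0.25, ][1L, ]
  Dv <- sleepdyn:::vlpo_drive(after$time_h, after$H, p)
  eq <- sleepdyn:::wake_branch(p, Dv)
  expect_lt(abs(after$V_v - eq$V_v), 0.05)
  expect_lt(abs(after$V_m - eq$V_m), 0.05)
})

test_that("wake samples have the MA dominating the VLPO away from transitions", {
  sim <- human_pr_sim()
  ts <- sim$timeseries[sim$timeseries$time_h > 48, ]
  ev <- sim$pattern$events$time_h
  near <- vapply(ts$time_h, function(t) any(abs(t - ev) < 0.25), logical(1))
  wake <- ts$state == "wake" & !near
  expect_true(all(ts$Q_m[wake] > ts$Q_v[wake]))
})

test_that("hard-switch and sigmoid transition times agree closely when calibrated", {
  sw <- pr_switch_human()
  sim_sw <- simulate_pr(sw, t_span = 24 * 6, init = "sleep")
  sim_pr <- human_pr_sim()
  m <- sleepdyn:::match_transitions(sim_sw$pattern, sim_pr$pattern, max_lag = 3)
  m <- m[m$time_a > 24, , drop = FALSE]
  expect_gte(nrow(m), 8L)
  # the sigmoid model leaves the vanished wake/sleep state through the
  # saddle-node ghost, which delays its firing-rate threshold crossing by
  # several minutes relative to the switch model
  expect_lt(max(abs(m$diff_h)), 0.25)
  expect_lt(mean(abs(m$diff_h)), 0.25)
})

test_that("an MA rate that never crosses 1/s is reported as a single-state run", {
  p <- pr_human(nu_vh = 0, D0_v = -5, circadian = circadian_waveform(0))
  sim <- simulate_pr(p, t_span = 6, init = "wake")
  expect_true(sim$pattern$truncated)
  expect_equal(nrow(sim$pattern$events), 0L)
  expect_true(all(sim$timeseries$state == "wake"))
})
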