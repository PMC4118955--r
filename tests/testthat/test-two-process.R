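test_that("flat-threshold episode durations match the closed form to 1e-9", {
  p <- flat_two_process()
  sim <- simulate_two_process(p, t_span = 24 * 6, H_init = 0.25,
                              state_init = "wake")
  ev <- sim$pattern$events
  durs <- diff(ev$time_h)
  first_dir <- ev$transition[1L]
  wake_durs <- durs[seq(ifelse(first_dir == "wake_to_sleep", 2, 1),
                        length(durs), by = 2)]
  sleep_durs <- durs[seq(ifelse(first_dir == "wake_to_sleep", 1, 2),
                         length(durs), by = 2)]
  expect_equal(unname(wake_durs), rep(18 * log(3), length(wake_durs)),
               tolerance = 1e-9)
  expect_equal(unname(sleep_durs), rep(4 * log(3), length(sleep_durs)),
               tolerance = 1e-9)
})

test_that("event-driven transitions agree with dense fixed-step integration", {
  p2 <- two_process_human()
  sim <- simulate_two_process(p2, t_span = 40, H_init = 13.5,
                              state_init = "wake")
  ev <- sim$pattern$events
  expect_gte(nrow(ev), 2L)
  # brute-force oracle: forward-Euler stepping at dt = 1e-4 h with grid
  # threshold detection
  dt <- 1e-4
  H <- 13.5; state <- "wake"; t <- 0
  found <- data.frame(time_h = numeric(0), transition = character(0))
  n <- ceiling(40 / dt)
  tt <- seq(0, by = dt, length.out = n)
  circ <- circadian_value(tt, p2$circadian)
  up <- p2$H0_plus + circ; lo <- p2$H0_minus + circ
  for (i in seq_len(n - 1L)) {
    dH <- if (state == "wake") (p2$mu - H) / p2$chi_w else -H / p2$chi_s
    H <- H + dt * dH
    if (state == "wake" && H > up[i + 1L]) {
      found <- rbind(found, data.frame(time_h = tt[i + 1L],
                                       transition = "wake_to_sleep"))
      state <- "sleep"
    } else if (state == "sleep" && H < lo[i + 1L]) {
      found <- rbind(found, data.frame(time_h = tt[i + 1L],
                                       transition = "sleep_to_wake"))
      state <- "wake"
    }
    if (nrow(found) >= nrow(ev)) break
  }
  k <- min(nrow(found), nrow(ev))
  expect_gte(k, 2L)
  expect_equal(found$transition[seq_len(k)], ev$transition[seq_len(k)])
  expect_lt(max(abs(found$time_h[seq_len(k)] - ev$time_h[seq_len(k)])), 1e-3)
})

test_that("human-equivalent defaults settle to a monophasic 24-h cycle", {
  p2 <- two_process_human()
  sim <- simulate_two_process(p2, t_span = 24 * 12)
  s <- classify_pattern(sim$pattern)
  expect_true(s$converged)
  expect_equal(s$period_days, 1)
  expect_equal(s$episodes_per_day, 1)
  expect_gt(s$daily_sleep_h, 6); expect_lt(s$daily_sleep_h, 11)
})

test_that("homeostat stays within [lower asymptote, mu] on the attractor", {
  p2 <- two_process_human()
  sim <- simulate_two_process(p2, t_span = 24 * 10)
  tail_ts <- sim$timeseries[sim$timeseries$time_h > 48, ]
  expect_true(all(tail_ts$H >= p2$lower_asymptote - 1e-9))
  expect_true(all(tail_ts$H <= p2$mu + 1e-9))
})

test_that("an unreachable upper threshold yields a truncated pattern, not an error", {
  expect_warning(
    p <- two_process_params(mu = 0.6, H0_plus = 0.75, H0_minus = 0.25,
                            chi_w = 18, chi_s = 4),
    "wake may never end")
  sim <- simulate_two_process(p, t_span = 24 * 5, H_init = 0.3,
                              state_init = "wake", max_wait_days = 3)
  expect_true(sim$pattern$truncated)
  expect_equal(nrow(sim$pattern$events), 0L)
})

test_that("a homeostat exactly on a threshold keeps its current state", {
  # start asleep exactly on the lower threshold at a phase where the
  # threshold falls faster than the homeostat: the tie resolves in favour of
  # sleep and no instantaneous switch is produced
  p2 <- two_process_human()
  H0 <- sleepdyn:::lower_threshold(0, p2)
  sim <- simulate_two_process(p2, t_span = 6, H_init = H0,
                              state_init = "sleep")
  ev <- sim$pattern$events
  expect_true(nrow(ev) == 0L || ev$time_h[1L] > 1)
})
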