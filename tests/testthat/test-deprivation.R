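test_that("protocol validation rejects malformed intervals", {
  expect_error(deprivation_protocol(matrix(c(0, 10, 5, 20), ncol = 2,
                                           byrow = TRUE)),
               "disjoint")
  expect_error(deprivation_protocol(matrix(c(10, 5), ncol = 2)), "end > start")
  expect_silent(deprivation_protocol(matrix(numeric(0), ncol = 2), t_span = 24))
})

test_that("an empty protocol reproduces the normal dynamics", {
  p2 <- two_process_human()
  empty <- deprivation_protocol(matrix(numeric(0), ncol = 2), t_span = 24 * 6)
  a <- simulate_deprived(p2, empty, t_span = 24 * 6)
  b <- simulate_two_process(p2, t_span = 24 * 6)
  expect_equal(a$pattern$events, b$pattern$events)
  expect_equal(a$timeseries$H, b$timeseries$H)
  # the slow-manifold PR engine cycles like its two-process equivalent
  d0 <- cached("pr_slow_baseline",
               simulate_deprived(pr_human(), empty, t_span = 24 * 8))
  s <- classify_pattern(d0$pattern)
  expect_equal(s$period_days, 1)
  expect_equal(s$episodes_per_day, 1)
  s2 <- classify_pattern(simulate_two_process(p2, t_span = 24 * 8,
                                              dt_out = 1)$pattern)
  expect_lt(abs(s$daily_sleep_h - s2$daily_sleep_h), 0.25)
})

test_that("four days of enforced wake: H rises towards mu with near-sleep dips", {
  wec <- human_effort_linear()
  p2 <- wec$params_2p
  ts <- wec$series
  # the homeostat remains strictly below the upper asymptote throughout
  expect_true(all(ts$H_2p < p2$mu))
  expect_true(all(ts$H < p2$mu * 1.1))
  # pressure ends far above its natural range and keeps increasing on average
  expect_gt(ts$H_2p[nrow(ts)], p2$H0_plus + 4)
  # circadian-gated dips bring the trajectory close to the moving threshold
  x <- ts$H_2p - sleepdyn:::upper_threshold(ts$time_h, p2)
  day1 <- ts$time_h < wec$t_onset + 36
  expect_lt(min(x[day1]), 0.1)     # gets very close to falling asleep
  expect_gt(max(x), 4)             # but is held awake far beyond the threshold
})

test_that("recovery sleep is longer than baseline but far shorter than the loss", {
  p2 <- two_process_human()
  base <- classify_pattern(simulate_two_process(p2, t_span = 24 * 8,
                                                dt_out = 1)$pattern)
  t_on <- 24 * 4 + 0.58
  prot <- deprivation_protocol(matrix(c(t_on, t_on + 96), ncol = 2),
                               t_span = t_on + 96 + 96)
  dep <- simulate_deprived(p2, prot, t_span = 24 * 13)
  ev <- dep$pattern$events
  ons <- ev$time_h[ev$transition == "wake_to_sleep"]
  rec_on <- ons[ons >= t_on + 96][1L]
  rec_off <- ev$time_h[ev$transition == "sleep_to_wake" & ev$time_h > rec_on][1L]
  rec <- rec_off - rec_on
  expect_gt(rec, base$daily_sleep_h + 1)   # longer than a baseline night
  expect_lt(rec, 24)                       # far shorter than the 96 h lost
})

test_that("efforts are zero-clamped, continuous, and start at zero", {
  wec <- human_effort_linear()
  ts <- wec$series
  expect_true(all(ts$effort_pr >= 0, na.rm = TRUE))
  expect_true(all(ts$effort_2p >= 0))
  # zero whenever the homeostat is below the nominal threshold
  below <- ts$H_minus_threshold < 0
  expect_true(all(ts$effort_pr[below] == 0, na.rm = TRUE))
  # effort vanishes at the deprivation start (the trajectory is on the threshold)
  expect_lt(ts$effort_pr[1L], 0.02)
  # continuity: no jumps beyond the drive slew over one output step
  expect_lt(max(abs(diff(ts$effort_pr)), na.rm = TRUE), 0.05)
  expect_lt(max(abs(diff(ts$effort_2p))), 0.05)
  # rising circadian-modulated envelope that flattens over days
  day <- pmin(floor((ts$time_h - wec$t_onset) / 24), 3)
  env <- as.numeric(tapply(ts$effort_pr, day, max, na.rm = TRUE))
  expect_true(all(diff(env) > 0))
  expect_lt(env[4L] - env[3L], env[2L] - env[1L])
})

test_that("the effort relation is near-linear, protocol-free and grid-stable", {
  p <- pr_human()
  rel <- cached("effort_relation", fit_effort_relation(p = p))
  expect_lt(rel$rel_rms, 0.02)
  # the quadratic coefficient is small against the linear one
  expect_lt(abs(rel$quadratic) / rel$linear, 0.05)
  # a doubled-density fold curve moves the coefficients by < 0.1%
  cv2 <- saddle_node_curve(p, seq(p$A, p$A + 8, by = 0.01))
  rel2 <- fit_effort_relation(cv2, p)
  expect_lt(abs(rel2$linear - rel$linear) / rel$linear, 1e-3)
  expect_lt(abs(rel2$quadratic - rel$quadratic) / abs(rel$quadratic), 2e-2)
  # insufficient fold-curve span is refused
  cv_short <- saddle_node_curve(p, seq(p$A, p$A + 0.5, by = 0.02))
  expect_error(fit_effort_relation(cv_short, p), "span")
})

test_that("wake can be extended much further than sleep", {
  spans <- cached("effort_spans", sleepdyn:::effort_spans(pr_human()))
  expect_gt(spans$wake_span, spans$sleep_span)
})

test_that("deep pressure excursions hit the fold-curve corner and become unavailable", {
  p <- pr_human()
  fpi <- sleepdyn:::fold_plus_interp(p)
  # beyond the largest attainable fold drive the effort is marked unavailable:
  # there wake cannot be maintained at any MA drive
  expect_gt(fpi$Dv_max, 100)   # far outside the physiological range
  ts_far <- data.frame(time_h = 0, H = (fpi$Dv_max + 5 - p$D0_v) / p$nu_vh)
  eff <- wake_effort_pr(p, ts_far)
  expect_true(is.na(eff$effort))
  # near the corner the MA drive needed per unit of VLPO drive is an order
  # of magnitude above its value on the physiological stretch
  s_low <- (fpi$D_m_of_Dv(fpi$Dv_plus0 + 5) - p$A) / 5
  dv_hi <- fpi$Dv_max - 5
  s_hi <- (fpi$D_m_of_Dv(fpi$Dv_max - 0.5) - fpi$D_m_of_Dv(dv_hi)) / 4.5
  expect_gt(s_hi / s_low, 10)
})

test_that("the linear asymptote form inflates day-4 effort by about a tenth; the saturating form does not", {
  lin <- human_effort_linear()
  sat <- human_effort_saturating()
  rd_lin <- abs(lin$day_ends$rel_diff[4L])
  rd_sat <- abs(sat$day_ends$rel_diff[4L])
  expect_gt(rd_lin, 0.05); expect_lt(rd_lin, 0.15)
  expect_lt(rd_sat, rd_lin)
  expect_lt(rd_sat, 0.05)
  # daily effort peaks of the two formulations stay within 15% throughout
  peaks <- function(w) tapply(w$series$effort_pr,
                              floor((w$series$time_h - w$t_onset) / 24), max)
  peaks2 <- function(w) tapply(w$series$effort_2p,
                               floor((w$series$time_h - w$t_onset) / 24), max)
  expect_true(all(abs(peaks(lin) - peaks2(lin)) / peaks2(lin) < 0.15))
  expect_true(all(abs(peaks(sat) - peaks2(sat)) / peaks2(sat) < 0.15))
})
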