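# the fine structure around the monophasic/biphasic transition is shared by
# several tests
fine_chi_scan <- function() {
  cached("fine_chi_scan",
         scan_parameter(two_process_human(), "chi",
                        values = seq(19.45, 18.8, by = -0.05),
                        transient_days = 25, max_period = 6))
}

test_that("patterns classify as monophasic, biphasic and period-two", {
  p2 <- two_process_human()
  mono <- classify_pattern(simulate_two_process(p2, t_span = 24 * 10,
                                                dt_out = 1)$pattern)
  expect_equal(mono$period_days, 1); expect_equal(mono$episodes_per_day, 1)

  p_bi <- sleepdyn:::apply_scan_param(p2, "chi", 18.8)
  bi <- classify_pattern(simulate_two_process(p_bi, t_span = 24 * 40,
                                              dt_out = 1)$pattern)
  expect_equal(bi$period_days, 1); expect_equal(bi$episodes_per_day, 2)
  # one longer and one short sleep per day
  si <- sleepdyn:::pattern_sleep_intervals(
    simulate_two_process(p_bi, t_span = 24 * 40, dt_out = 1)$pattern)
  durs <- si[, 2L] - si[, 1L]
  durs <- tail(durs, 4)
  expect_gt(max(durs) / min(durs), 1.5)

  sc <- fine_chi_scan()
  p2w <- sc$summary[sc$summary$period_days == 2 & sc$summary$converged, ]
  expect_gte(nrow(p2w), 1L)
  expect_equal(unique(p2w$episodes_per_day), 1.5)
})

test_that("decreasing chi adds sleep episodes in order, with steady daily sleep", {
  sc <- cached("coarse_chi_scan",
               scan_parameter(two_process_human(), "chi",
                              values = seq(45, 9, by = -3),
                              transient_days = 20, max_period = 6))
  s <- sc$summary[sc$summary$converged, ]
  expect_gte(nrow(s), 10L)
  # episodes per day never decrease as chi falls
  expect_true(all(diff(s$episodes_per_day) > -1e-9))
  expect_gt(max(s$episodes_per_day), 2.9)
  # total daily sleep stays within a physiological band throughout
  expect_true(all(s$daily_sleep_h > 6 & s$daily_sleep_h < 10))
  # episode-adding brackets are flagged
  expect_gte(nrow(sc$critical[sc$critical$type == "episode-adding", ]), 2L)
})

test_that("a period-two window separates monophasic and biphasic sleep", {
  sc <- fine_chi_scan()
  s <- sc$summary
  i2 <- which(s$period_days == 2 & s$converged)
  expect_gte(length(i2), 1L)
  # the window lies between a monophasic value above and a biphasic value below
  expect_true(any(s$episodes_per_day[seq_len(min(i2) - 1L)] == 1))
  expect_true(any(s$episodes_per_day[seq(max(i2) + 1L, nrow(s))] == 2))
  # inside the window the onset sequence repeats every three onsets (three
  # sleep episodes per two-day cycle), not every onset
  chi2 <- s$value[i2[1L]]
  p_w <- sleepdyn:::apply_scan_param(two_process_human(), "chi", chi2)
  it <- iterate_map(p_w, 0.6, n = 30)
  mods <- tail(it$t_onset_mod, 7)
  expect_lt(max(abs(sleepdyn:::circ_diff(mods[c(4, 7)], mods[1L]))), 0.05)
  expect_gt(abs(sleepdyn:::circ_diff(mods[2L], mods[1L])), 0.5)
  # three consecutive onsets span exactly one two-day cycle
  expect_equal(diff(it$t_onset[c(nrow(it) - 3L, nrow(it))]), 48,
               tolerance = 1e-3)
})

test_that("threshold shifts end in no-wake and no-sleep with >24 h episodes near the boundaries", {
  sc <- cached("shift_scan",
               scan_parameter(two_process_human(), "threshold_shift",
                              values = seq(-19, 10, by = 2.9),
                              transient_days = 20, max_period = 6))
  s <- sc$summary
  expect_equal(s$regime[1L], "no_wake")
  expect_equal(s$regime[nrow(s)], "no_sleep")
  mid <- s[s$regime == "cycling" & s$converged, ]
  # daily sleep decreases monotonically as the thresholds rise
  expect_true(all(diff(mid$daily_sleep_h) < 0))
  # cycles near the no-wake boundary carry sleep episodes longer than a day
  pb <- sleepdyn:::apply_scan_param(two_process_human(), "threshold_shift", -17)
  simb <- simulate_two_process(pb, t_span = 24 * 40, dt_out = 1)
  ev <- simb$pattern$events
  expect_gt(max(diff(ev$time_h)), 24)
})

test_that("grazing bifurcations are located with tangency certificates", {
  gz <- cached("human_grazing",
               locate_grazing(two_process_human(), "chi", c(24, 15),
                              param_tol = 2e-4, transient_days = 25,
                              max_period = 4))
  expect_gt(gz$critical, 15); expect_lt(gz$critical, 24)
  cert <- gz$certificate
  expect_lt(cert$min_distance, 1e-4)
  expect_lt(abs(cert$tangency_slope), 0.02)
  # the map discontinuity sits on the diagonal at the grazing parameter
  expect_lt(cert$map_diag_gap_h, 0.05)
})

test_that("no grazing arises without circadian modulation", {
  p2 <- two_process_human()
  p2$circadian <- circadian_waveform(0)
  # episode durations vary smoothly with the threshold shift and the map
  # never develops a discontinuity: there is nothing to graze
  shifts <- seq(-0.2, 0.2, by = 0.05)
  wake_durs <- vapply(shifts, function(d) {
    pd <- sleepdyn:::apply_scan_param(p2, "threshold_shift", d)
    nx <- next_onset(pd, 3)
    nx$t_next - nx$t_wake
  }, numeric(1))
  expect_lt(max(abs(diff(diff(wake_durs)))), 0.01)   # smooth, no jumps
  rm0 <- build_return_map(p2, n_grid = 48)
  expect_equal(nrow(rm0$discontinuities), 0L)
})

test_that("a bracket without an episode-count change is rejected", {
  expect_error(locate_grazing(two_process_human(), "chi", c(45, 40),
                              transient_days = 10, max_period = 2),
               "equal episode counts")
})

test_that("two-process and PR chi scans find the same transition shifted by the fixed asymptote", {
  gz2p <- cached("human_grazing",
                 locate_grazing(two_process_human(), "chi", c(24, 15),
                                param_tol = 2e-4, transient_days = 25,
                                max_period = 4))
  gzpr <- cached("pr_grazing",
                 locate_grazing(pr_human(), "chi", c(20, 13),
                                param_tol = 0.1, transient_days = 12,
                                max_period = 2, certify = FALSE))
  # the fixed-asymptote policy shifts the monophasic/biphasic transition:
  # the PR model loses monophasic sleep at a smaller chi than its fixed-mu
  # two-process equivalent, by a known systematic margin
  expect_lt(gzpr$critical, gz2p$critical)
  expect_gt(gzpr$critical, 0.6 * gz2p$critical)
})

test_that("per-point recalibration reproduces the default-point equivalence", {
  sc <- scan_parameter(two_process_human(), "chi", values = c(45, 44),
                       transient_days = 10, max_period = 2,
                       recalibrate = TRUE, source_pr = pr_human())
  expect_true(all(sc$summary$episodes_per_day == 1))
  expect_error(scan_parameter(two_process_human(), "chi", c(45, 44),
                              recalibrate = TRUE), "source_pr")
})
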