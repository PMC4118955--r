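test_that("next_onset matches a direct multi-day simulation", {
  p2 <- two_process_human()
  for (t0 in c(0.58, 5, 16.5)) {
    nx <- next_onset(p2, t0)
    sim <- simulate_two_process(p2, t_span = 24 * 3 + t0,
                                H_init = sleepdyn:::upper_threshold(t0, p2),
                                state_init = "sleep", t_start = t0)
    ons <- sleepdyn:::pattern_onsets(sim$pattern)
    expect_lt(abs(nx$t_next - ons[1L]), 1e-6)
  }
})

test_that("the human-default map has one flat stable fixed point", {
  rm_ <- cached("human_map", build_return_map(two_process_human(), n_grid = 96))
  fp <- rm_$fixed_points
  expect_equal(nrow(fp), 1L)
  expect_true(fp$stable[1L])
  expect_lt(abs(fp$slope[1L]), 0.2)
  nx <- next_onset(two_process_human(), fp$t_star[1L])
  expect_lt(abs(sleepdyn:::circ_diff(nx$t_next_mod, fp$t_star[1L])), 1e-4)
})

test_that("onsets straddling the discontinuity diverge by hours", {
  rm_ <- cached("human_map", build_return_map(two_process_human(), n_grid = 96))
  d <- rm_$discontinuities
  expect_equal(nrow(d), 1L)
  expect_gt(abs(d$jump[1L]), 1)
  a <- next_onset(two_process_human(), (d$location[1L] - 1e-3) %% 24)
  b <- next_onset(two_process_human(), (d$location[1L] + 1e-3) %% 24)
  expect_gt(abs(sleepdyn:::circ_diff(a$t_next_mod, b$t_next_mod)), 1)
})

test_that("without circadian modulation the map is a rigid shift", {
  p2 <- two_process_human()
  p2$circadian <- circadian_waveform(0)
  cycle <- p2$chi_w * log((p2$mu - p2$H0_minus) / (p2$mu - p2$H0_plus)) +
    p2$chi_s * log(p2$H0_plus / p2$H0_minus)
  rm_ <- build_return_map(p2, n_grid = 48)
  expect_equal(nrow(rm_$discontinuities), 0L)
  expect_equal(rm_$grid$t_next, (rm_$grid$t_onset + cycle) %% 24,
               tolerance = 1e-6)
})

test_that("iterates from spread starting onsets converge to one attractor", {
  p2 <- two_process_human()
  limits <- vapply(seq(0.5, 23.5, length.out = 10), function(t0) {
    it <- iterate_map(p2, t0, n = 8)
    expect_true(attr(it, "converged"))
    lim <- attr(it, "limit")
    # within a few days the onset has settled to the attractor
    expect_lt(abs(sleepdyn:::circ_diff(it$t_onset_mod[it$iter == 5L], lim)),
              0.01)
    lim
  }, numeric(1))
  expect_lt(max(abs(sleepdyn:::circ_diff(limits, limits[1L]))), 1e-3)
  # starting at the fixed point produces a constant sequence
  it0 <- iterate_map(p2, limits[1L], n = 4)
  expect_lt(max(abs(sleepdyn:::circ_diff(it0$t_onset_mod, limits[1L]))), 1e-3)
})

test_that("map interpolation matches the exact map away from discontinuities", {
  # the map inherits a square-root-like steepening on the approach to the
  # tangency, so sub-millihour interpolation accuracy needs a fine grid and
  # a buffer around the discontinuity
  rm_ <- build_return_map(two_process_human(), n_grid = 240)
  set.seed(42)
  t0s <- runif(200, 0, 24)
  d <- rm_$discontinuities$location
  keep <- vapply(t0s, function(t) all(abs(sleepdyn:::circ_diff(t, d)) > 1),
                 logical(1))
  t0s <- t0s[keep]
  pred <- predict_return_map(rm_, t0s)
  exact <- vapply(t0s, function(t) next_onset(two_process_human(), t)$t_next_mod,
                  numeric(1))
  expect_lt(max(abs(sleepdyn:::circ_diff(pred, exact))), 1e-3)
})

test_that("each discontinuity corresponds to a threshold tangency", {
  rm_ <- cached("human_map_fine",
                build_return_map(two_process_human(), n_grid = 96,
                                 refine_tol = 1e-8))
  expect_gte(nrow(rm_$discontinuities), 1L)
  for (td in rm_$discontinuities$location) {
    dmin <- min(sleepdyn:::tangency_distance(two_process_human(), (td - 1e-7) %% 24),
                sleepdyn:::tangency_distance(two_process_human(), (td + 1e-7) %% 24))
    expect_lt(dmin, 1e-6)
  }
})

test_that("no-sleep regimes are reported as divergent, not mapped", {
  p2 <- two_process_human()
  p2$H0_plus <- p2$H0_plus + 12; p2$H0_minus <- p2$H0_minus + 12
  nx <- next_onset(p2, 3, max_days = 5)
  expect_equal(nx$regime, "no_sleep")
  expect_true(is.na(nx$t_next))
  it <- iterate_map(p2, 3, n = 3)
  expect_equal(attr(it, "regime"), "no_sleep")
})
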