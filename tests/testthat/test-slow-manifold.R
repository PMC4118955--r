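test_that("solution count changes 1 -> 3 -> 1 across the bistable band", {
  p <- pr_human()
  f <- sleepdyn:::fold_points(p, p$A)
  expect_equal(nrow(f), 2L)
  Dvm <- min(f$D_v); Dvp <- max(f$D_v)
  counts <- vapply(c(Dvm - 0.5, (Dvm + Dvp) / 2, Dvp + 0.5),
                   function(d) nrow(slow_manifold_solve(p, d)), integer(1))
  expect_equal(counts, c(1L, 3L, 1L))
  # all solutions satisfy both equilibrium equations
  sols <- slow_manifold_solve(p, (Dvm + Dvp) / 2)
  expect_true(all(sols$residual < 1e-8))
})

test_that("branches far from the band are the expected single states", {
  p <- pr_human()
  hi <- slow_manifold_solve(p, D_v = 10)   # strong VLPO drive: sleep only
  expect_equal(nrow(hi), 1L)
  expect_equal(hi$branch, "sleep")
  expect_gt(hi$Q_v, hi$Q_m)
  lo <- slow_manifold_solve(p, D_v = -5)   # weak drive: wake only
  expect_equal(nrow(lo), 1L)
  expect_equal(lo$branch, "wake")
  expect_gt(lo$Q_m, lo$Q_v)
})

test_that("fold locations agree with a brute-force solution-count bisection", {
  p <- pr_human()
  f <- sleepdyn:::fold_points(p, p$A)
  # independent oracle: count sign changes of the reduced scalar equation on
  # a very fine potential grid (resolves the root pair collapsing at the fold)
  count_roots <- function(Dv, Vv_center) {
    vv <- seq(Vv_center - 4, Vv_center + 4, length.out = 80001L)
    Fv <- vv - Dv + p$nu_vm *
      firing_rate(p$A - p$nu_mv * firing_rate(vv, p), p)
    sum(Fv[-1L] * Fv[-length(Fv)] < 0)
  }
  for (i in seq_len(nrow(f))) {
    dv <- f$D_v[i]; vc <- f$V_v[i]
    n_lo <- count_roots(dv - 0.01, vc)
    lo <- dv - 0.01; hi <- dv + 0.01
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (count_roots(mid, vc) == n_lo) lo <- mid else hi <- mid
    }
    expect_lt(abs((lo + hi) / 2 - dv), 1e-6)
  }
})

test_that("fold points satisfy equilibrium and tangency conditions", {
  p <- pr_human()
  f <- sleepdyn:::fold_points(p, p$A)
  for (i in seq_len(nrow(f))) {
    Vv <- f$V_v[i]; Vm <- f$V_m[i]; Dv <- f$D_v[i]
    expect_lt(abs(Vv - Dv + p$nu_vm * firing_rate(Vm, p)), 1e-8)
    expect_lt(abs(Vm - p$A + p$nu_mv * firing_rate(Vv, p)), 1e-8)
    tang <- 1 - p$nu_vm * p$nu_mv *
      firing_rate_deriv(Vm, p) * firing_rate_deriv(Vv, p)
    expect_lt(abs(tang), 1e-8)
  }
})

test_that("the saddle-node curve brackets the hysteresis loop and is ordered", {
  p <- pr_human()
  cv <- saddle_node_curve(p, seq(p$A, p$A + 3, by = 0.1))
  ok <- !is.na(cv$D_v_plus)
  expect_true(all(ok))
  expect_true(all(cv$D_v_minus < cv$D_v_plus))
  # the normal cycle's drive range lies inside the default-point folds
  sim <- human_pr_sim()
  ts <- sim$timeseries[sim$timeseries$time_h > 48, ]
  Dv <- sleepdyn:::vlpo_drive(ts$time_h, ts$H, p)
  expect_gt(max(Dv), cv$D_v_plus[1L] - 0.05)  # reaches the wake-loss fold
  expect_lt(min(Dv), cv$D_v_minus[1L] + 0.05) # reaches the sleep-loss fold
})

test_that("the hard switch has no smooth folds", {
  cv <- saddle_node_curve(pr_switch_human(), seq(1.3, 3, by = 0.5))
  expect_true(isTRUE(attr(cv, "no_folds")))
  expect_true(all(is.na(cv$D_v_plus)))
})
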