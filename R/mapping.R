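# ---- equivalence machinery: hard-switch model <-> two-process model ---------

#' Map hard-switch model parameters to two-process parameters
#'
#' On the slow manifold, the hard-switch mutual-inhibition model is exactly a
#' two-process model: during wake the homeostat relaxes towards
#' \eqn{\mu = P(\bar Q)} and during sleep towards \eqn{P(0) = 0}, both with
#' time constant \eqn{\chi}, and the switching conditions
#' \eqn{V_v = V_{th}} translate into circadian-modulated pressure
#' thresholds
#' \deqn{H_0^+ = (V_{th} + \nu_{vm}\bar Q - D_{0v})/\nu_{vh}, \qquad
#'       H_0^- = (V_{th} - D_{0v})/\nu_{vh},}
#' with threshold modulation \eqn{-C(t)/\nu_{vh}} (the drive-side circadian
#' waveform, rescaled and sign-flipped). The threshold gap
#' \eqn{\nu_{vm}\bar Q/\nu_{vh}} is the amount by which the MA inhibits the
#' firing of the VLPO during wake: the hysteresis of the flip-flop.
#'
#' @param p A \code{\link{pr_switch_params}} object.
#' @return A \code{\link{two_process_params}} object with
#'   \eqn{\chi_w = \chi_s = \chi}.
#' @seealso \code{\link{calibrate_switch_from_pr}} for obtaining
#'   \code{Q_bar}, \code{V_th} from the full sigmoid model.
#' @export
pr_switch_to_two_process <- function(p) {
  stopifnot(inherits(p, "pr_switch_params"))
  H0p <- (p$V_th + p$nu_vm * p$Q_bar - p$D0_v) / p$nu_vh
  H0m <- (p$V_th - p$D0_v) / p$nu_vh
  if (H0m >= H0p)
    stop("pr_switch_to_two_process: mapped thresholds satisfy H0_minus >= ",
         "H0_plus (nu_vm * Q_bar must be positive: the MA must inhibit the ",
         "VLPO for the switch to be hysteretic)", call. = FALSE)
  circ <- p$circadian
  circ2 <- circadian_waveform(-circ$amplitude / p$nu_vh,
                              period = 2 * pi / circ$omega,
                              phase = circ$phase, harmonics = circ$harmonics)
  two_process_params(mu = h_production(p$Q_bar, p),
                     H0_plus = H0p, H0_minus = H0m,
                     chi_w = p$chi, chi_s = p$chi,
                     circadian = circ2,
                     lower_asymptote = h_production(0, p))
}

# inverse of the production function: Q such that P(Q) = mu
production_inverse <- function(mu, p) {
  if (identical(p$asymptote_form, "saturating")) {
    if (mu >= p$mu_sat)
      stop("production_inverse: requested asymptote exceeds the saturating ",
           "production ceiling", call. = FALSE)
    mu * p$Q_half / (p$mu_sat - mu)
  } else mu / p$mu_h
}

# quadratic-interpolated extremum of a sampled series around index i
refine_extremum <- function(tt, hh, i) {
  if (i <= 1L || i >= length(tt)) return(c(tt[i], hh[i]))
  t3 <- tt[(i - 1L):(i + 1L)]; h3 <- hh[(i - 1L):(i + 1L)]
  fit <- stats::lm.fit(cbind(1, t3 - t3[2L], (t3 - t3[2L])^2), h3)
  b <- unname(fit$coefficients)
  if (abs(b[3L]) < 1e-14) return(c(tt[i], hh[i]))
  dt <- -b[2L] / (2 * b[3L])
  c(t3[2L] + dt, b[1L] + b[2L] * dt + b[3L] * dt^2)
}

#' Calibrate hard-switch parameters from the sigmoid model
#'
#' Implements the three-step reduction of the full sigmoid mutual-inhibition
#' model to its hard-switch (and hence two-process) equivalent, valid for
#' monophasic cycles away from bifurcation points:
#' \enumerate{
#'   \item identify the two-process thresholds with the saddle-node drives of
#'     the slow manifold at the nominal MA drive:
#'     \eqn{H_0^\pm = (D_v^\pm - D_{0v})/\nu_{vh}}, hence
#'     \eqn{V_{th} = D_v^-};
#'   \item integrate the model over one converged cycle, extract the
#'     homeostat extrema (quadratically interpolated) and their times, and
#'     solve for the upper asymptote \eqn{\mu} so that the wake-phase
#'     exponential passes through both extrema; then
#'     \eqn{\bar Q = P^{-1}(\mu)};
#'   \item take the lower asymptote as 0 for the sleep phase, and set the
#'     switch-model inhibition \eqn{\nu_{vm}^{sw} = (D_v^+ - D_v^-)/\bar Q}
#'     so the mapped threshold gap matches the fold separation.
#' }
#' The resulting two-process trajectory retains the timings and values of the
#' homeostat extrema of the source model. Because only a small part of the
#' sigmoid is used, \eqn{\bar Q} comes out close to the mean population firing
#' rate during wake, far below \eqn{Q_{max}}. The calibrated asymptote
#' retains some dependence on \eqn{\chi} (through the portion of the firing
#' curve a cycle visits); this is reported, not bounded.
#'
#' If the nominal MA drive does not exceed the calibrated switch voltage, the
#' switch model's MA could never turn on; the calibration then raises the
#' switch model's \code{A} to \code{V_th + 0.5} mV (this only enters through
#' the sign of \eqn{V_m - V_{th}} and does not affect the equivalence).
#'
#' @param p A \code{\link{pr_params}} (sigmoid) or \code{pr_switch_params}
#'   object; for the latter the calibration is an (exact) fixed point.
#' @param transient_days,cycle_days Days discarded and simulated for the
#'   extrema extraction.
#' @param report If \code{TRUE}, cross-simulate the mapped two-process model
#'   against the source over \code{compare_days} and attach the per-transition
#'   discrepancies.
#' @param compare_days Days used for the equivalence report.
#' @return List of class \code{pr_calibration} with elements \code{switch}
#'   (a \code{pr_switch_params}), \code{two_process}
#'   (a \code{two_process_params}), \code{extrema} (times and values of the
#'   homeostat extrema used), and, if requested, \code{report}
#'   (an \code{equivalence_report}).
#' @export
calibrate_switch_from_pr <- function(p, transient_days = 8, cycle_days = 4,
                                     report = TRUE, compare_days = 10) {
  stopifnot(inherits(p, "pr_params"))
  is_switch <- inherits(p, "pr_switch_params")
  # step 1: transition drives
  if (is_switch) {
    Dvm <- p$V_th
    Dvp <- p$V_th + p$nu_vm * p$Q_bar
  } else {
    f <- fold_points(p, p$A)
    if (nrow(f) < 2L)
      stop("calibrate_switch_from_pr: no bistable band at the nominal MA ",
           "drive; cannot identify thresholds", call. = FALSE)
    Dvm <- min(f$D_v); Dvp <- max(f$D_v)
  }
  # step 2: converged cycle and homeostat extrema
  t_span <- 24 * (transient_days + cycle_days)
  sim <- simulate_pr(p, t_span = t_span, init = "wake")
  summ <- classify_pattern(sim$pattern, max_period = 2)
  if (!(summ$converged && summ$period_days == 1 && summ$episodes_per_day == 1))
    stop("calibrate_switch_from_pr: source model is not on a converged ",
         "monophasic cycle; the asymptote-matching step is only valid away ",
         "from bifurcation points", call. = FALSE)
  ev <- sim$pattern$events
  on_t <- ev$time_h[ev$transition == "wake_to_sleep"]
  off_t <- ev$time_h[ev$transition == "sleep_to_wake"]
  s2 <- on_t[length(on_t)]
  w1 <- max(off_t[off_t < s2])
  s1 <- max(on_t[on_t < w1])
  ts <- sim$timeseries
  win_max <- ts$time_h > w1 & ts$time_h < s2 + 1
  win_min <- ts$time_h > s1 & ts$time_h < w1 + 1
  imax <- which(win_max)[which.max(ts$H[win_max])]
  imin <- which(win_min)[which.min(ts$H[win_min])]
  emax <- refine_extremum(ts$time_h, ts$H, imax)
  emin <- refine_extremum(ts$time_h, ts$H, imin)
  dt_w <- emax[1L] - emin[1L]
  E <- exp(-dt_w / p$chi)
  mu <- (emax[2L] - emin[2L] * E) / (1 - E)
  Q_bar <- production_inverse(mu, p)
  V_th <- Dvm
  nu_vm_sw <- (Dvp - Dvm) / Q_bar
  A_sw <- if (p$A > V_th) p$A else V_th + 0.5
  sw <- pr_switch_params(Q_max = p$Q_max, theta = p$theta, sigma = p$sigma,
                         nu_vm = nu_vm_sw, nu_mv = p$nu_mv, nu_vh = p$nu_vh,
                         D0_v = p$D0_v, A = A_sw, chi = p$chi, mu_h = p$mu_h,
                         tau = p$tau, circadian = p$circadian,
                         asymptote_form = p$asymptote_form,
                         Q_half = p$Q_half, mu_sat = p$mu_sat,
                         Q_bar = Q_bar, V_th = V_th)
  p2 <- pr_switch_to_two_process(sw)
  out <- structure(list(switch = sw, two_process = p2,
                        extrema = list(t_min = emin[1L], H_min = emin[2L],
                                       t_max = emax[1L], H_max = emax[2L]),
                        fold_drives = c(D_v_minus = Dvm, D_v_plus = Dvp),
                        source = p),
                   class = "pr_calibration")
  if (report)
    out$report <- equivalence_report(sim, p2, compare_days = compare_days)
  out
}

#' @export
print.pr_calibration <- function(x, ...) {
  cat("Calibration of the hard-switch / two-process equivalent\n")
  cat(sprintf("  fold drives: D_v- = %.4f, D_v+ = %.4f mV\n",
              x$fold_drives[1L], x$fold_drives[2L]))
  cat(sprintf("  Q_bar = %.4f /s, V_th = %.4f mV\n",
              x$switch$Q_bar, x$switch$V_th))
  cat(sprintf("  two-process: mu = %.4f, H0+ = %.4f, H0- = %.4f, chi = %.4g h\n",
              x$two_process$mu, x$two_process$H0_plus, x$two_process$H0_minus,
              x$two_process$chi_w))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

# pair each event of pattern a with the nearest same-direction event of b
match_transitions <- function(pat_a, pat_b, max_lag = 6) {
  ea <- pat_a$events; eb <- pat_b$events
  rows <- lapply(seq_len(nrow(ea)), function(i) {
    cand <- eb$time_h[eb$transition == ea$transition[i]]
    if (!length(cand)) return(NULL)
    j <- which.min(abs(cand - ea$time_h[i]))
    if (abs(cand[j] - ea$time_h[i]) > max_lag) return(NULL)
    data.frame(time_a = ea$time_h[i], time_b = cand[j],
               diff_h = cand[j] - ea$time_h[i],
               transition = ea$transition[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Equivalence report: source simulation vs mapped two-process model
#'
#' Simulates the mapped two-process model from an initial condition matched to
#' the source run (same absolute time and homeostat value at the source's last
#' sleep onset) and tabulates the per-transition time discrepancies and the
#' homeostat-extrema discrepancies over \code{compare_days}.
#'
#' @param sim A \code{sleep_sim} from \code{\link{simulate_pr}} (the source).
#' @param p2 The mapped \code{\link{two_process_params}}.
#' @param compare_days Days compared.
#' @return Object of class \code{equivalence_report}: list with
#'   \code{transitions} (data frame of matched transition times and
#'   differences in hours), \code{max_abs_diff_h}, \code{mean_abs_diff_h},
#'   and \code{extrema_diff} (pressure discrepancies at the homeostat
#'   extrema).
#' @export
equivalence_report <- function(sim, p2, compare_days = 10) {
  ev <- sim$pattern$events
  on_t <- ev$time_h[ev$transition == "wake_to_sleep"]
  if (!length(on_t))
    stop("equivalence_report: source run has no sleep onset", call. = FALSE)
  t0 <- on_t[length(on_t)]
  H0 <- sim$timeseries$H[which.min(abs(sim$timeseries$time_h - t0))]
  sim2 <- simulate_two_process(p2, t_span = 24 * compare_days, H_init = H0,
                               state_init = "sleep", t_start = t0)
  # continue the source model over the comparison window
  y_end <- sim$timeseries[nrow(sim$timeseries), ]
  src2 <- simulate_pr(sim$params, t_span = t0 + 24 * compare_days -
                        y_end$time_h + 24, init = c(y_end$V_v, y_end$V_m, y_end$H),
                      t_start = y_end$time_h)
  pat_src <- sleep_wake_pattern(
    c(ev$time_h, src2$pattern$events$time_h),
    c(ev$transition, src2$pattern$events$transition),
    sim$pattern$t_start, src2$pattern$t_end)
  keep <- pat_src$events$time_h >= t0 & pat_src$events$time_h <= t0 + 24 * compare_days
  pat_src$events <- pat_src$events[keep, ]
  m <- match_transitions(pat_src, sim2$pattern)
  # homeostat extrema discrepancy: compare H at matched sleep onsets
  ons <- m[m$transition == "wake_to_sleep", , drop = FALSE]
  extr <- if (nrow(ons)) {
    Ha <- vapply(ons$time_a, function(t) {
      src <- if (t <= max(sim$timeseries$time_h)) sim else src2
      src$timeseries$H[which.min(abs(src$timeseries$time_h - t))]
    }, numeric(1))
    Hb <- upper_threshold(ons$time_b, p2)
    Hb - Ha
  } else numeric(0)
  structure(list(transitions = m,
                 max_abs_diff_h = if (is.null(m)) NA_real_ else max(abs(m$diff_h)),
                 mean_abs_diff_h = if (is.null(m)) NA_real_ else mean(abs(m$diff_h)),
                 extrema_diff = extr,
                 two_process = p2),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("Equivalence report: %d matched transitions, max |dt| = %.3f h, mean |dt| = %.3f h\n",
              if (is.null(x$transitions)) 0L else nrow(x$transitions),
              x$max_abs_diff_h, x$mean_abs_diff_h))
  invisible(x)
}
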