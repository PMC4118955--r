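# ---- sleep deprivation and wake effort --------------------------------------

#' Sleep-deprivation protocol
#'
#' A set of enforced-wake intervals within a simulation span.
#'
#' @param intervals Two-column matrix or data frame of (start, end) times in
#'   hours; intervals must be ordered, disjoint and lie within the span.
#' @param t_span Total span of the experiment in hours (defaults to the end
#'   of the last interval).
#' @return Object of class \code{deprivation_protocol}.
#' @export
deprivation_protocol <- function(intervals, t_span = NULL) {
  m <- as.matrix(intervals)
  if (length(m) == 0L) m <- matrix(numeric(0), ncol = 2)
  if (ncol(m) != 2L)
    stop("deprivation_protocol: 'intervals' needs columns (start, end)", call. = FALSE)
  if (nrow(m)) {
    if (any(m[, 2L] <= m[, 1L]))
      stop("deprivation_protocol: intervals must have end > start", call. = FALSE)
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
      stop("deprivation_protocol: intervals must be ordered and disjoint", call. = FALSE)
  }
  if (is.null(t_span)) t_span <- if (nrow(m)) max(m[, 2L]) else 0
  if (nrow(m) && max(m[, 2L]) > t_span + 1e-9)
    stop("deprivation_protocol: intervals must lie within 't_span'", call. = FALSE)
  structure(list(intervals = m, t_span = t_span),
            class = "deprivation_protocol")
}

#' Simulate under a sleep-deprivation protocol
#'
#' During enforced-wake intervals the model is kept awake regardless of the
#' homeostatic pressure; outside them, normal switching resumes.
#' For the two-process model this means the homeostat continues along the
#' wake exponential past the upper threshold -- equivalently, the upper
#' threshold is continuously moved to keep the model awake. By construction
#' the homeostat can never exceed the upper asymptote (the approach is
#' asymptotic), so no failure mode exists here.
#'
#' For the sigmoid mutual-inhibition model the simulation runs on the slow
#' manifold: the state follows the wake branch and, once the VLPO drive
#' exceeds the wake-loss fold \eqn{D_v^+}, the wake state is preserved by
#' following the saddle-node boundary in the \eqn{(D_v, D_m)} plane (the
#' "ghost" of the wake state; see \code{\link{wake_effort_pr}} for the drive
#' this requires). The MA firing rate feeding the homeostatic production is
#' then held at the fully-awake rate \eqn{Q_{ref}} -- the maximum wake-branch
#' rate attained over the converged undeprived cycle -- reflecting that the
#' effort restores normal waking function; with the linear production form
#' the upper asymptote consequently runs above its episode-averaged
#' calibrated value, while the saturating form is insensitive to the
#' difference.
#'
#' @param p \code{\link{two_process_params}} or sigmoid
#'   \code{\link{pr_params}}.
#' @param protocol A \code{\link{deprivation_protocol}} (possibly empty, in
#'   which case the run is identical to a normal simulation with the same
#'   engine).
#' @param t_span Simulation span (hours); defaults to the protocol span.
#' @param H_init,state_init,t_start,dt_out As in the simulators.
#' @return A \code{sleep_sim} object (for the PR model the time series has
#'   columns \code{time_h, H, Q_m, state}; the fast potentials are not
#'   tracked on the slow manifold).
#' @export
simulate_deprived <- function(p, protocol, ...) UseMethod("simulate_deprived")

#' @rdname simulate_deprived
#' @export
simulate_deprived.two_process_params <- function(p, protocol, t_span = NULL,
                                                 H_init = NULL,
                                                 state_init = "wake",
                                                 t_start = 0, dt_out = 0.01,
                                                 ...) {
  stopifnot(inherits(protocol, "deprivation_protocol"))
  if (is.null(t_span)) t_span <- max(protocol$t_span - t_start, 24)
  if (is.null(H_init)) H_init <- (p$H0_plus + p$H0_minus) / 2
  prot <- if (nrow(protocol$intervals)) protocol$intervals else NULL
  core <- sim_two_process_core(p, t_start, t_start + t_span, H_init,
                               state_init, protocol = prot)
  sim <- build_two_process_sim(core, p, t_start, t_start + t_span,
                               state_init, dt_out)
  sim$protocol <- protocol
  sim
}

# slow-manifold firing-rate interpolators for the deprived PR engine
sm_rate_tables <- function(p) {
  key <- paste0("smrates_", paste(signif(unlist(p[c("Q_max", "theta", "sigma",
        "nu_vm", "nu_mv", "A")]), 12), collapse = "_"))
  hit <- .sleepdyn_cache[[key]]
  if (!is.null(hit)) return(hit)
  fp <- fold_points(p, p$A)
  if (nrow(fp) < 2L)
    stop("sm_rate_tables: no bistable band at the nominal drives", call. = FALSE)
  Dvm <- min(fp$D_v); Dvp <- max(fp$D_v)
  lo <- Dvm - 25; hi <- Dvp + 25
  gw <- seq(lo, Dvp, length.out = 400L)
  qw <- vapply(gw, function(d) {
    b <- wake_branch(p, d, p$A)
    if (is.null(b)) NA_real_ else b$Q_m
  }, numeric(1))
  gs <- seq(Dvm, hi, length.out = 400L)
  qs <- vapply(gs, function(d) {
    b <- sleep_branch(p, d, p$A)
    if (is.null(b)) NA_real_ else b$Q_m
  }, numeric(1))
  res <- list(D_v_minus = Dvm, D_v_plus = Dvp,
              Qm_wake = stats::approxfun(gw, qw, rule = 2),
              Qm_sleep = stats::approxfun(gs, qs, rule = 2))
  .sleepdyn_cache[[key]] <- res
  res
}

#' @rdname simulate_deprived
#' @export
simulate_deprived.pr_params <- function(p, protocol, t_span = NULL,
                                        H_init = NULL, state_init = "wake",
                                        t_start = 0, dt_out = 0.02, ...) {
  stopifnot(inherits(protocol, "deprivation_protocol"))
  if (inherits(p, "pr_switch_params"))
    stop("simulate_deprived: the hard-switch model has no fold to follow; ",
         "use the sigmoid model or the two-process formulation", call. = FALSE)
  if (is.null(t_span)) t_span <- max(protocol$t_span - t_start, 24)
  tb <- sm_rate_tables(p)
  if (is.null(H_init))
    H_init <- if (p$nu_vh > 0) -(p$D0_v) / p$nu_vh
    else h_production(firing_rate(p$A, p), p)
  # fully-awake reference rate: maximum wake-branch rate over the undeprived
  # converged cycle (the rate the effort restores during enforced wake)
  Q_ref <- sm_reference_rate(p, tb)
  prot <- protocol$intervals
  enforced <- function(t) {
    if (!nrow(prot)) return(FALSE)
    any(prot[, 1L] <= t & t < prot[, 2L])
  }
  t_end <- t_start + t_span
  rhs <- function(t, y, parms) {
    Dv <- vlpo_drive(t, y[1L], p)
    Qm <- if (parms$state == "wake") {
      if (Dv <= tb$D_v_plus) tb$Qm_wake(Dv)
      else if (parms$enforced) Q_ref
      else tb$Qm_wake(tb$D_v_plus)
    } else tb$Qm_sleep(Dv)
    list((h_production(Qm, p) - y[1L]) / p$chi, Q_m = Qm)
  }
  rootfun <- function(t, y, parms) {
    Dv <- vlpo_drive(t, y[1L], p)
    if (parms$state == "wake") Dv - tb$D_v_plus else Dv - tb$D_v_minus
  }
  t <- t_start; H <- H_init; state <- state_init
  rows <- list(); row_states <- character(0)
  ev_t <- numeric(0); ev_dir <- character(0)
  state0 <- state
  while (t < t_end - 1e-9) {
    # stop times: protocol boundaries and span end
    bounds <- sort(unique(c(prot[prot[, 1L] > t + 1e-9, 1L],
                            prot[prot[, 2L] > t + 1e-9, 2L], t_end)))
    t1 <- bounds[1L]
    enf <- enforced(t)
    if (enf && state == "sleep") {
      ev_t <- c(ev_t, t); ev_dir <- c(ev_dir, "sleep_to_wake"); state <- "wake"
    }
    parms <- list(state = state, enforced = enf)
    times <- seq(t, t1, by = dt_out)
    if (length(times) < 2L || times[length(times)] < t1)
      times <- unique(c(times, t1))
    out <- if (enf)
      deSolve::ode(y = c(H = H), times = times, func = rhs, parms = parms,
                   rtol = 1e-9, atol = 1e-9)
    else
      deSolve::lsodar(y = c(H = H), times = times, func = rhs, parms = parms,
                      rootfunc = rootfun, rtol = 1e-9, atol = 1e-9)
    blk <- out[-nrow(out), , drop = FALSE]
    rows[[length(rows) + 1L]] <- blk
    row_states <- c(row_states, rep(parms$state, nrow(blk)))
    t_hit <- out[nrow(out), 1L]
    H <- out[nrow(out), 2L]
    hit_root <- !enf && !is.null(attr(out, "troot")) && length(attr(out, "troot")) &&
      t_hit < t1 - 1e-9
    if (hit_root) {
      ev_dir <- c(ev_dir, if (state == "wake") "wake_to_sleep" else "sleep_to_wake")
      ev_t <- c(ev_t, t_hit)
      state <- if (state == "wake") "sleep" else "wake"
      t <- t_hit + 1e-9
    } else {
      if (t_hit >= t_end - 1e-9) {
        rows[[length(rows)]] <- out
        row_states <- c(row_states, parms$state)
        break
      }
      t <- t_hit
      # leaving an enforced interval with pressure beyond the fold: sleep
      if (enf && !enforced(t + 1e-9) && state == "wake" &&
          vlpo_drive(t, H, p) > tb$D_v_plus) {
        ev_t <- c(ev_t, t); ev_dir <- c(ev_dir, "wake_to_sleep"); state <- "sleep"
      }
    }
  }
  traj <- do.call(rbind, rows)
  keep <- !duplicated(traj[, 1L])
  ts <- data.frame(time_h = traj[keep, 1L], H = traj[keep, 2L],
                   Q_m = traj[keep, 3L], state = row_states[keep],
                   stringsAsFactors = FALSE)
  pat <- sleep_wake_pattern(ev_t, ev_dir, t_start, t_end, state_start = state0,
                            truncated = FALSE)
  structure(list(model = "pr_slow", params = p, timeseries = ts, pattern = pat,
                 protocol = protocol, Q_ref = Q_ref),
            class = "sleep_sim")
}

# maximum wake-branch MA rate over the converged undeprived cycle
sm_reference_rate <- function(p, tb = sm_rate_tables(p)) {
  key <- paste0("qref_", paste(signif(unlist(p[c("Q_max", "theta", "sigma",
        "nu_vm", "nu_mv", "nu_vh", "D0_v", "A", "chi", "mu_h")]), 12),
        collapse = "_"), "_", p$asymptote_form)
  hit <- .sleepdyn_cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- simulate_deprived_baseline(p, tb)
  .sleepdyn_cache[[key]] <- base
  base
}

# run the undeprived slow-manifold engine long enough to converge and return
# the maximum wake Q_m of the final two days
simulate_deprived_baseline <- function(p, tb, days = 10) {
  t_end <- 24 * days
  H <- -(p$D0_v) / p$nu_vh
  state <- "wake"; t <- 0
  qmax <- -Inf
  rhs <- function(t, y, parms) {
    Dv <- vlpo_drive(t, y[1L], p)
    Qm <- if (parms$state == "wake") tb$Qm_wake(min(Dv, tb$D_v_plus))
    else tb$Qm_sleep(Dv)
    list((h_production(Qm, p) - y[1L]) / p$chi, Q_m = Qm)
  }
  rootfun <- function(t, y, parms) {
    Dv <- vlpo_drive(t, y[1L], p)
    if (parms$state == "wake") Dv - tb$D_v_plus else Dv - tb$D_v_minus
  }
  while (t < t_end - 1e-9) {
    parms <- list(state = state)
    times <- seq(t, t_end, by = 0.02)
    if (length(times) < 2L) break
    out <- deSolve::lsodar(y = c(H = H), times = times, func = rhs,
                           parms = parms, rootfunc = rootfun,
                           rtol = 1e-9, atol = 1e-9)
    t_hit <- out[nrow(out), 1L]; H <- out[nrow(out), 2L]
    if (state == "wake" && t > t_end - 72)
      qmax <- max(qmax, max(out[, 3L]))
    if (t_hit >= t_end - 1e-9) break
    state <- if (state == "wake") "sleep" else "wake"
    t <- t_hit + 1e-9
  }
  if (!is.finite(qmax)) firing_rate(p$A, p) else qmax
}

#' Wake effort in the mutual-inhibition model
#'
#' The additional MA drive needed to preserve the wake state once the VLPO
#' drive exceeds the wake-loss fold: following the saddle-node boundary in
#' the \eqn{(D_v, D_m)} plane,
#' \eqn{\Delta D_m(t) = D_m^{fold}(D_v(t)) - A}, clipped at zero below the
#' fold. Beyond the largest \eqn{D_v^+} the fold curve attains (its
#' "corner"), wake cannot be maintained at all and the effort is reported as
#' \code{NA}.
#'
#' @param p Sigmoid \code{\link{pr_params}}.
#' @param ts Either a \code{sleep_sim} from \code{\link{simulate_deprived}}
#'   or a data frame with columns \code{time_h} and \code{H}.
#' @return Data frame \code{time_h, D_v, effort} (mV).
#' @export
wake_effort_pr <- function(p, ts) {
  stopifnot(inherits(p, "pr_params"))
  if (inherits(p, "pr_switch_params"))
    stop("wake_effort_pr: the hard switch has no smooth fold curve", call. = FALSE)
  if (inherits(ts, "sleep_sim")) ts <- ts$timeseries
  fpi <- fold_plus_interp(p)
  Dv <- vlpo_drive(ts$time_h, ts$H, p)
  eff <- ifelse(Dv <= fpi$Dv_plus0, 0,
                ifelse(Dv > fpi$Dv_max, NA_real_, fpi$D_m_of_Dv(Dv) - p$A))
  data.frame(time_h = ts$time_h, D_v = Dv, effort = eff)
}

#' Fit the effort-versus-pressure relation
#'
#' Least-squares fit of the fold-following wake effort \eqn{\Delta D_m}
#' against the pressure excess \eqn{x = H - H^+} (equivalently
#' \eqn{(D_v - D_v^+)/\nu_{vh}}), as a linear-plus-quadratic function through
#' the origin. The relation depends only on the model geometry (the shape of
#' the fold curve), not on any protocol; it is close to linear with a small
#' quadratic coefficient.
#'
#' @param curve A \code{\link{saddle_node_curve}} spanning the nominal MA
#'   drive upwards, or \code{NULL} to build one from \code{p}.
#' @param p Sigmoid \code{\link{pr_params}}.
#' @param x_max Upper end of the fit window in pressure units (default 7,
#'   spanning roughly the pressure excess reached after four days of total
#'   deprivation at the human defaults).
#' @return Object of class \code{effort_relation}: list with \code{linear}
#'   and \code{quadratic} coefficients (mV per pressure unit and per squared
#'   unit), \code{rms} and \code{rel_rms} residual diagnostics, and the fit
#'   window.
#' @export
fit_effort_relation <- function(curve = NULL, p, x_max = 7) {
  stopifnot(inherits(p, "pr_params"))
  if (is.null(curve))
    curve <- saddle_node_curve(p, seq(p$A, p$A + 8, by = 0.02))
  stopifnot(inherits(curve, "saddle_node_curve"))
  ok <- !is.na(curve$D_v_plus) & curve$D_m >= p$A
  if (sum(ok) < 10L)
    stop("fit_effort_relation: fold curve does not span the nominal MA drive",
         call. = FALSE)
  dm <- curve$D_m[ok]; dvp <- curve$D_v_plus[ok]
  o <- order(dm); dm <- dm[o]; dvp <- dvp[o]
  last <- which(diff(dvp) <= 0)[1L]
  if (!is.na(last)) { dm <- dm[1:last]; dvp <- dvp[1:last] }
  x <- (dvp - dvp[1L]) / p$nu_vh
  W <- dm - dm[1L]
  keep <- x <= x_max
  if (max(x[keep]) < 0.8 * x_max)
    stop("fit_effort_relation: fold curve span is insufficient for the ",
         "requested fit window", call. = FALSE)
  x <- x[keep]; W <- W[keep]
  fit <- stats::lm(W ~ 0 + x + I(x^2))
  res <- stats::residuals(fit)
  structure(list(linear = unname(stats::coef(fit)[1L]),
                 quadratic = unname(stats::coef(fit)[2L]),
                 rms = sqrt(mean(res^2)),
                 rel_rms = sqrt(mean(res^2)) / diff(range(W)),
                 x_max = x_max, n = length(x)),
            class = "effort_relation")
}

#' @export
print.effort_relation <- function(x, ...) {
  cat(sprintf("Effort relation: W = %.4f x %+.5f x^2 (mV per pressure unit), rel RMS %.3g\n",
              x$linear, x$quadratic, x$rel_rms))
  invisible(x)
}

#' Wake effort in the two-process formulation
#'
#' Applies the fitted linear-plus-quadratic relation to the excess of the
#' homeostat over the (unmoved) upper threshold; zero whenever the homeostat
#' is below the threshold.
#'
#' @param p2 \code{\link{two_process_params}}.
#' @param relation An \code{\link{fit_effort_relation}} result.
#' @param H Homeostat values (pressure units).
#' @param t Times (hours) at which the threshold is evaluated.
#' @return Effort values in mV (zero-clamped).
#' @export
wake_effort_two_process <- function(p2, relation, H, t) {
  stopifnot(inherits(p2, "two_process_params"),
            inherits(relation, "effort_relation"))
  x <- H - upper_threshold(t, p2)
  ifelse(x > 0, pmax(0, relation$linear * x + relation$quadratic * x^2), 0)
}

# achievable drive spans for extending wake (raising D_m along the upper
# fold) and extending sleep (lowering D_m along the lower fold); the sleep
# side is more restricted at the default parameters
effort_spans <- function(p, span = 10, step = 0.05) {
  up <- saddle_node_curve(p, seq(p$A, p$A + span, by = step))
  dn <- saddle_node_curve(p, seq(p$A, max(p$A - span, 1e-3), by = -step))
  wake_span <- max(up$D_v_plus, na.rm = TRUE) - up$D_v_plus[1L]
  sleep_span <- dn$D_v_minus[1L] - min(dn$D_v_minus, na.rm = TRUE)
  list(wake_span = wake_span, sleep_span = sleep_span)
}

#' Compare the two wake-effort formulations over a deprivation protocol
#'
#' Runs a total sleep-deprivation experiment of \code{days} days starting at
#' the natural sleep onset, in both formulations: (i) the sigmoid
#' mutual-inhibition model on the slow manifold, with the effort obtained
#' from the saddle-node (ghost-state) construction, and (ii) the equivalent
#' two-process model (calibrated from the same PR parameters, with fixed
#' asymptotes) with the effort from the fitted pressure relation. The
#' production form of \code{p} (\code{asymptote_form}) governs the PR side;
#' the two-process side always uses the fixed calibrated asymptote.
#'
#' @param p Sigmoid \code{\link{pr_params}}.
#' @param days Length of enforced wakefulness (days).
#' @param dt_out Output step (hours).
#' @param calibration Optional precomputed \code{\link{calibrate_switch_from_pr}}
#'   result for \code{p} (saves recomputation).
#' @return Object of class \code{wake_effort_result}: list with
#'   \code{series} (data frame \code{time_h, H, H_2p, H_minus_threshold,
#'   effort_pr, effort_2p, rel_diff}), \code{relation}, \code{day_ends}
#'   (data frame of efforts and relative difference at each 24-h mark),
#'   \code{t_onset} and the parameter objects. \code{rel_diff} is
#'   \code{(effort_pr - effort_2p)/effort_2p}, reported where the two-process
#'   effort is positive.
#' @export
wake_effort_compare <- function(p = pr_human(), days = 4, dt_out = 0.05,
                                calibration = NULL) {
  stopifnot(inherits(p, "pr_params"), !inherits(p, "pr_switch_params"))
  cal <- if (is.null(calibration)) calibrate_switch_from_pr(p, report = FALSE)
  else calibration
  p2 <- cal$two_process
  # converged natural sleep onset of the two-process equivalent
  base <- simulate_two_process(p2, t_span = 24 * 12, dt_out = 1)
  ons <- pattern_onsets(base$pattern)
  t_on <- ons[length(ons)]
  H_on <- upper_threshold(t_on, p2)
  prot <- deprivation_protocol(matrix(c(t_on, t_on + 24 * days), ncol = 2),
                               t_span = t_on + 24 * days)
  dep2 <- simulate_deprived(p2, prot, t_span = 24 * days, H_init = H_on,
                            state_init = "wake", t_start = t_on,
                            dt_out = dt_out)
  depP <- simulate_deprived(p, prot, t_span = 24 * days, H_init = H_on,
                            state_init = "wake", t_start = t_on,
                            dt_out = dt_out)
  relation <- fit_effort_relation(p = p)
  tt <- dep2$timeseries$time_h
  H2 <- dep2$timeseries$H
  HP <- stats::approx(depP$timeseries$time_h, depP$timeseries$H, xout = tt)$y
  effP <- wake_effort_pr(p, data.frame(time_h = tt, H = HP))$effort
  eff2 <- wake_effort_two_process(p2, relation, H2, tt)
  rel <- ifelse(eff2 > 1e-6, (effP - eff2) / eff2, NA_real_)
  series <- data.frame(time_h = tt, H = HP, H_2p = H2,
                       H_minus_threshold = HP - upper_threshold(tt, p2),
                       effort_pr = effP, effort_2p = eff2, rel_diff = rel)
  at_day <- function(d) {
    i <- which.min(abs(tt - (t_on + 24 * d)))
    data.frame(day = d, effort_pr = effP[i], effort_2p = eff2[i],
               rel_diff = rel[i])
  }
  day_ends <- do.call(rbind, lapply(seq_len(days), at_day))
  structure(list(series = series, relation = relation, day_ends = day_ends,
                 t_onset = t_on, params_pr = p, params_2p = p2),
            class = "wake_effort_result")
}

#' @export
print.wake_effort_result <- function(x, ...) {
  cat("Wake-effort comparison (PR saddle-node vs two-process relation)\n")
  print(x$day_ends, row.names = FALSE)
  invisible(x)
}
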