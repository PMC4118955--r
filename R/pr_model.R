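# ---- full mutual-inhibition model integration -------------------------------

# default initial states: relaxed wake / sleep fast states with mid-range H
pr_default_init <- function(p, state = c("wake", "sleep")) {
  state <- match.arg(state)
  # drive-neutral pressure level; with the homeostatic coupling removed fall
  # back to the waking production equilibrium
  H <- if (p$nu_vh > 0) -(p$D0_v) / p$nu_vh
  else h_production(firing_rate(p$A, p), p)
  if (state == "wake") c(V_v = -12, V_m = p$A, H = H)
  else c(V_v = 2, V_m = -8, H = H)
}

#' Simulate the mutual-inhibition model
#'
#' Integrates the full three-variable flip-flop model (VLPO and MA potentials
#' plus homeostatic pressure) with a stiff solver. The wake/sleep label is
#' derived from the MA firing rate crossing the conventional threshold of
#' 1/s; crossing times are refined by root-finding on the dense solver
#' output in both directions. For \code{\link{pr_switch_params}} the hard
#' switch makes the vector field discontinuous, so the integration proceeds
#' mode-by-mode with event location at the switch voltage.
#'
#' @param p A \code{\link{pr_params}} or \code{\link{pr_switch_params}}
#'   object.
#' @param t_span Length of the simulation (hours).
#' @param init \code{"wake"}, \code{"sleep"}, or a numeric vector
#'   \code{c(V_v, V_m, H)}.
#' @param t_start Start time (hours); anchors the circadian phase.
#' @param dt_out Output step (hours).
#' @param rtol,atol Solver tolerances.
#' @return Object of class \code{sleep_sim} with \code{timeseries} columns
#'   \code{time_h, H, V_v, V_m, Q_v, Q_m, state} and a
#'   \code{\link{sleep_wake_pattern}}. If the MA rate never crosses 1/s the
#'   pattern is a truncated single-state pattern.
#' @export
simulate_pr <- function(p, t_span = 24 * 15, init = "wake", t_start = 0,
                        dt_out = 0.005, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(p, "pr_params"))
  y0 <- if (is.character(init)) pr_default_init(p, init) else {
    stopifnot(length(init) == 3L)
    c(V_v = init[[1L]], V_m = init[[2L]], H = init[[3L]])
  }
  if (inherits(p, "pr_switch_params"))
    simulate_pr_switch(p, y0, t_start, t_span, dt_out, rtol, atol)
  else
    simulate_pr_sigmoid(p, y0, t_start, t_span, dt_out, rtol, atol)
}

simulate_pr_sigmoid <- function(p, y0, t_start, t_span, dt_out, rtol, atol) {
  tau_h <- p$tau / 3600
  rhs <- function(t, y, parms) {
    Qm <- firing_rate(y[2L], p)
    Dv <- vlpo_drive(t, y[3L], p)
    list(c((-y[1L] - p$nu_vm * Qm + Dv) / tau_h,
           (-y[2L] - p$nu_mv * firing_rate(y[1L], p) + p$A) / tau_h,
           (h_production(Qm, p) - y[3L]) / p$chi))
  }
  times <- seq(t_start, t_start + t_span, by = dt_out)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop(sprintf("simulate_pr: integrator failed near t = %.4f h",
                 max(out[, 1L])), call. = FALSE)
  tt <- out[, 1L]
  Qm <- firing_rate(out[, 3L], p)
  # refine Q_m = 1 crossings on the dense output (both directions)
  f <- Qm - 1
  idx <- which(f[-1L] * f[-length(f)] < 0)
  Vm_fun <- stats::splinefun(tt, out[, 3L], method = "natural")
  ev_t <- vapply(idx, function(i)
    uniroot(function(s) firing_rate(Vm_fun(s), p) - 1,
            c(tt[i], tt[i + 1L]), tol = 1e-10)$root, numeric(1))
  ev_dir <- ifelse(f[idx] > 0, "wake_to_sleep", "sleep_to_wake")
  state0 <- if (f[1L] > 0) "wake" else "sleep"
  ts <- data.frame(time_h = tt, H = out[, 4L], V_v = out[, 2L], V_m = out[, 3L],
                   Q_v = firing_rate(out[, 2L], p), Q_m = Qm,
                   state = label_states(tt, ev_t, ev_dir, state0),
                   stringsAsFactors = FALSE)
  pat <- sleep_wake_pattern(ev_t, ev_dir, t_start, t_start + t_span,
                            state_start = state0,
                            truncated = length(ev_t) == 0L)
  structure(list(model = "pr", params = p, timeseries = ts, pattern = pat),
            class = "sleep_sim")
}

label_states <- function(tt, ev_t, ev_dir, state0) {
  st <- rep(state0, length(tt))
  if (!length(ev_t)) return(st)
  states <- c(state0, ifelse(ev_dir == "wake_to_sleep", "sleep", "wake"))
  idx <- findInterval(tt, ev_t) + 1L
  states[idx]
}

# hard-switch model: piecewise-linear fast dynamics, integrated mode by mode
# with root events at the switch voltage
simulate_pr_switch <- function(p, y0, t_start, t_span, dt_out, rtol, atol) {
  tau_h <- p$tau / 3600
  t_end <- t_start + t_span
  make_rhs <- function(v_on, m_on) {
    function(t, y, parms) {
      Qm <- if (m_on) p$Q_bar else 0
      Qv <- if (v_on) p$Q_bar else 0
      Dv <- vlpo_drive(t, y[3L], p)
      list(c((-y[1L] - p$nu_vm * Qm + Dv) / tau_h,
             (-y[2L] - p$nu_mv * Qv + p$A) / tau_h,
             (h_production(Qm, p) - y[3L]) / p$chi))
    }
  }
  rootfun <- function(t, y, parms) c(y[1L] - p$V_th, y[2L] - p$V_th)
  v_on <- y0[1L] > p$V_th
  m_on <- y0[2L] > p$V_th
  t <- t_start; y <- y0
  rows <- list(); ev_t <- numeric(0); ev_dir <- character(0)
  state0 <- if (m_on) "wake" else "sleep"
  while (t < t_end - 1e-9) {
    times <- seq(t, t_end, by = dt_out)
    if (length(times) < 2L) times <- c(t, t_end)
    out <- deSolve::lsodar(y = y, times = times, func = make_rhs(v_on, m_on),
                           parms = NULL, rootfunc = rootfun,
                           rtol = rtol, atol = atol)
    rows[[length(rows) + 1L]] <- out[-nrow(out), , drop = FALSE]
    troot <- attr(out, "troot")
    y <- out[nrow(out), 2:4]
    t_hit <- out[nrow(out), 1L]
    if (is.null(troot) || !length(troot) || t_hit >= t_end - 1e-9) {
      rows[[length(rows)]] <- out   # keep the final row on the last segment
      break
    }
    which_root <- which(attr(out, "iroot") == 1)[1L]
    if (is.na(which_root)) which_root <- 1L
    if (which_root == 1L) {          # VLPO crosses the switch voltage
      v_on <- !v_on
    } else {                         # MA crosses the switch voltage
      m_on <- !m_on
      ev_t <- c(ev_t, t_hit)
      ev_dir <- c(ev_dir, if (m_on) "sleep_to_wake" else "wake_to_sleep")
    }
    # nudge past the event so the root is not re-detected at the restart
    h <- 1e-7
    dy <- unlist(make_rhs(v_on, m_on)(t_hit, y, NULL)[[1L]])
    y <- y + h * dy
    t <- t_hit + h
  }
  traj <- do.call(rbind, rows)
  traj <- traj[!duplicated(traj[, 1L]), , drop = FALSE]
  tt <- traj[, 1L]
  Qv <- ifelse(traj[, 2L] > p$V_th, p$Q_bar, 0)
  Qm <- ifelse(traj[, 3L] > p$V_th, p$Q_bar, 0)
  ts <- data.frame(time_h = tt, H = traj[, 4L], V_v = traj[, 2L],
                   V_m = traj[, 3L], Q_v = Qv, Q_m = Qm,
                   state = label_states(tt, ev_t, ev_dir, state0),
                   stringsAsFactors = FALSE)
  pat <- sleep_wake_pattern(ev_t, ev_dir, t_start, t_end,
                            state_start = state0,
                            truncated = length(ev_t) == 0L)
  structure(list(model = "pr_switch", params = p, timeseries = ts, pattern = pat),
            class = "sleep_sim")
}
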