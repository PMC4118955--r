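# ---- closed-form homeostat dynamics -----------------------------------------
# During wake H relaxes towards mu, during sleep towards the lower asymptote,
# both exponentially.  All simulation machinery below works with these closed
# forms plus root-finding for the threshold crossings; no ODE stepping is
# involved, so transition times are limited only by root tolerance.

h_wake <- function(t, t0, H0, p) p$mu + (H0 - p$mu) * exp(-(t - t0) / p$chi_w)

h_sleep <- function(t, t0, H0, p) {
  la <- p$lower_asymptote
  la + (H0 - la) * exp(-(t - t0) / p$chi_s)
}

# First strict crossing of f through zero from below (dir = +1) or above
# (dir = -1) on (t0, t_max]; scans in chunks, refines with uniroot.
# Returns NA when no crossing is found.
find_crossing <- function(f, t0, t_max, dir = 1, step = 0.005) {
  chunk <- 48
  lo <- t0
  f_lo <- dir * f(lo)
  while (lo < t_max) {
    hi <- min(lo + chunk, t_max)
    tt <- seq(lo, hi, by = step)
    if (tt[length(tt)] < hi) tt <- c(tt, hi)
    ft <- dir * f(tt)
    ft[1L] <- f_lo                       # carry the sign at the chunk edge
    pos <- which(ft > 0)
    pos <- pos[pos > 1L]
    hit <- pos[ft[pos - 1L] <= 0][1L]
    if (!is.na(hit)) {
      g <- function(t) dir * f(t)
      if (g(tt[hit - 1L]) == 0) return(tt[hit - 1L])
      return(uniroot(g, c(tt[hit - 1L], tt[hit]), tol = 1e-12)$root)
    }
    f_lo <- ft[length(ft)]
    lo <- hi
  }
  NA_real_
}

# core event-driven integrator; protocol is an optional matrix of enforced
# wake intervals (columns start, end)
sim_two_process_core <- function(p, t_start, t_end, H_init, state_init,
                                 protocol = NULL, max_wait_days = 40,
                                 scan_step = 0.005) {
  segs <- list()    # each: list(t0, t1, H0, state)
  ev_t <- numeric(0); ev_dir <- character(0)
  truncated <- FALSE

  push_seg <- function(t0, t1, H0, state)
    segs[[length(segs) + 1L]] <<- list(t0 = t0, t1 = t1, H0 = H0, state = state)
  H_at_end <- function(s)
    if (s$state == "wake") h_wake(s$t1, s$t0, s$H0, p) else h_sleep(s$t1, s$t0, s$H0, p)

  enforced_at <- function(t) {
    if (is.null(protocol) || !nrow(protocol)) return(NA_integer_)
    i <- which(protocol[, 1L] <= t & t < protocol[, 2L])
    if (length(i)) i[1L] else NA_integer_
  }
  next_enforced_start <- function(t) {
    if (is.null(protocol) || !nrow(protocol)) return(Inf)
    s <- protocol[protocol[, 1L] > t, 1L]
    if (length(s)) min(s) else Inf
  }

  t <- t_start; H <- H_init; state <- state_init
  while (t < t_end - 1e-12) {
    ienf <- enforced_at(t)
    if (!is.na(ienf)) {
      # enforced wake until the interval end (or span end)
      if (state == "sleep") {        # forced awakening
        ev_t <- c(ev_t, t); ev_dir <- c(ev_dir, "sleep_to_wake")
        state <- "wake"
      }
      t1 <- min(protocol[ienf, 2L], t_end)
      push_seg(t, t1, H, "wake")
      H <- h_wake(t1, t, H, p); t <- t1
      if (t < t_end - 1e-12 && H > upper_threshold(t, p)) {
        ev_t <- c(ev_t, t); ev_dir <- c(ev_dir, "wake_to_sleep")
        state <- "sleep"
      }
      next
    }
    # a state inconsistent with the thresholds (possible for supplied initial
    # conditions) switches immediately; exact equality keeps the current state
    if (state == "wake" && H > upper_threshold(t, p) &&
        (!length(ev_t) || ev_t[length(ev_t)] < t)) {
      ev_t <- c(ev_t, t); ev_dir <- c(ev_dir, "wake_to_sleep")
      state <- "sleep"
      next
    }
    if (state == "sleep" && H < lower_threshold(t, p) &&
        (!length(ev_t) || ev_t[length(ev_t)] < t)) {
      ev_t <- c(ev_t, t); ev_dir <- c(ev_dir, "sleep_to_wake")
      state <- "wake"
      next
    }
    horizon <- min(t_end, t + 24 * max_wait_days, next_enforced_start(t))
    if (state == "wake") {
      f <- function(s) h_wake(s, t, H, p) - upper_threshold(s, p)
      tc <- find_crossing(f, t, horizon, dir = 1, step = scan_step)
    } else {
      f <- function(s) h_sleep(s, t, H, p) - lower_threshold(s, p)
      tc <- find_crossing(f, t, horizon, dir = -1, step = scan_step)
    }
    if (is.na(tc)) {
      if (horizon < t_end && is.finite(next_enforced_start(t)) &&
          horizon == next_enforced_start(t)) {
        push_seg(t, horizon, H, state)
        H <- H_at_end(segs[[length(segs)]]); t <- horizon
        next
      }
      push_seg(t, min(horizon, t_end), H, state)
      if (horizon < t_end) truncated <- TRUE
      t <- t_end
      break
    }
    push_seg(t, tc, H, state)
    H <- if (state == "wake") upper_threshold(tc, p) else lower_threshold(tc, p)
    ev_dir <- c(ev_dir, if (state == "wake") "wake_to_sleep" else "sleep_to_wake")
    ev_t <- c(ev_t, tc)
    state <- if (state == "wake") "sleep" else "wake"
    t <- tc
  }
  list(segments = segs, event_times = ev_t, event_dirs = ev_dir,
       truncated = truncated, state_final = state, H_final = H,
       t_final = t)
}

# evaluate H of a core result at arbitrary times (vectorised)
core_eval_H <- function(core, t, p) {
  starts <- vapply(core$segments, `[[`, numeric(1), "t0")
  idx <- findInterval(t, starts)
  idx[idx < 1L] <- 1L
  vapply(seq_along(t), function(i) {
    s <- core$segments[[idx[i]]]
    if (s$state == "wake") h_wake(t[i], s$t0, s$H0, p)
    else h_sleep(t[i], s$t0, s$H0, p)
  }, numeric(1))
}

core_eval_state <- function(core, t) {
  starts <- vapply(core$segments, `[[`, numeric(1), "t0")
  idx <- findInterval(t, starts)
  idx[idx < 1L] <- 1L
  vapply(idx, function(i) core$segments[[i]]$state, character(1))
}

#' Simulate the two-process model
#'
#' Event-driven simulation using the piecewise closed-form exponentials of the
#' homeostat: within an episode \eqn{H(t)} is evaluated analytically and the
#' switching times are obtained by root-finding on
#' \eqn{H(t) - H^\pm(t)}, not by grid detection. Wake-to-sleep transitions
#' occur only at the upper threshold, sleep-to-wake only at the lower
#' threshold; a homeostat exactly on a threshold stays in its current state
#' (strict-crossing tie-break).
#'
#' @param p A \code{\link{two_process_params}} object.
#' @param t_span Length of the simulation in hours.
#' @param H_init Initial homeostatic pressure (default: midway between the
#'   mean thresholds). Must be non-negative.
#' @param state_init \code{"wake"} or \code{"sleep"}.
#' @param t_start Start time in hours; sets the circadian phase, since the
#'   waveform is anchored to absolute time.
#' @param dt_out Output sampling step (hours) for the returned time series.
#' @param max_wait_days If no threshold crossing occurs within this many days
#'   the pattern is reported as truncated (e.g. permanent wake when \eqn{\mu}
#'   lies below the threshold band), not as an error.
#' @param scan_step Scan step (hours) used to bracket crossings before
#'   root refinement; small enough to catch near-grazing double crossings.
#' @return Object of class \code{sleep_sim}: list with \code{timeseries}
#'   (data frame \code{time_h}, \code{H}, \code{state}), \code{pattern}
#'   (a \code{\link{sleep_wake_pattern}}), \code{params}, and \code{model =
#'   "two_process"}.
#' @examples
#' p <- two_process_params(mu = 1, H0_plus = 0.75, H0_minus = 0.25,
#'                         chi_w = 18, chi_s = 4)
#' sim <- simulate_two_process(p, t_span = 100)
#' # with no circadian modulation the episode durations are exact logarithms:
#' # wake 18*log(3) h, sleep 4*log(3) h
#' @export
simulate_two_process <- function(p, t_span = 24 * 20, H_init = NULL,
                                 state_init = c("wake", "sleep"),
                                 t_start = 0, dt_out = 0.01,
                                 max_wait_days = 40, scan_step = 0.005) {
  stopifnot(inherits(p, "two_process_params"))
  state_init <- match.arg(state_init)
  if (is.null(H_init)) H_init <- max(0, (p$H0_plus + p$H0_minus) / 2)
  if (H_init < 0) stop("simulate_two_process: 'H_init' must be >= 0", call. = FALSE)
  t_end <- t_start + t_span
  core <- sim_two_process_core(p, t_start, t_end, H_init, state_init,
                               max_wait_days = max_wait_days,
                               scan_step = scan_step)
  build_two_process_sim(core, p, t_start, t_end, state_init, dt_out)
}

build_two_process_sim <- function(core, p, t_start, t_end, state_init, dt_out) {
  tt <- seq(t_start, t_end, by = dt_out)
  ts <- data.frame(time_h = tt,
                   H = core_eval_H(core, tt, p),
                   state = core_eval_state(core, tt),
                   stringsAsFactors = FALSE)
  pat <- sleep_wake_pattern(core$event_times, core$event_dirs,
                            t_start, t_end, state_start = state_init,
                            truncated = core$truncated)
  structure(list(model = "two_process", params = p, timeseries = ts,
                 pattern = pat, core = core),
            class = "sleep_sim")
}

#' @export
print.sleep_sim <- function(x, ...) {
  cat(sprintf("%s simulation over [%.1f, %.1f] h, %d transitions\n",
              x$model, min(x$timeseries$time_h), max(x$timeseries$time_h),
              nrow(x$pattern$events)))
  invisible(x)
}
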