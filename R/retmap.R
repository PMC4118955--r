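# ---- first-return map of sleep-onset times (two-process model) --------------

# signed circular difference on the 24-h circle, in (-12, 12]
circ_diff <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Next sleep onset of the two-process model
#'
#' Starting on the upper threshold at time \code{t_onset} (the homeostat is
#' set to \eqn{H^+(t_{onset})}), propagates the model through one sleep and
#' one wake episode and returns the time of the next wake-to-sleep
#' transition. This is the exact evaluation underlying the first-return map.
#'
#' @param p \code{\link{two_process_params}}.
#' @param t_onset Sleep-onset time in hours (absolute; the value modulo 24
#'   fixes the circadian phase).
#' @param max_days Horizon in days after which a non-returning trajectory is
#'   declared divergent.
#' @param scan_step Crossing-scan step (hours).
#' @return List with \code{t_next} (absolute hours), \code{t_next_mod}
#'   (modulo 24), \code{days_elapsed} (whole days between onsets),
#'   \code{t_wake} (the intervening sleep-to-wake time) and \code{regime}
#'   (\code{"ok"}, \code{"no_wake"} or \code{"no_sleep"}; for the latter two
#'   the times are \code{NA}).
#' @export
next_onset <- function(p, t_onset, max_days = 40, scan_step = 0.005) {
  stopifnot(inherits(p, "two_process_params"))
  H0 <- upper_threshold(t_onset, p)
  f_s <- function(s) h_sleep(s, t_onset, H0, p) - lower_threshold(s, p)
  t_w <- find_crossing(f_s, t_onset, t_onset + 24 * max_days, dir = -1,
                       step = scan_step)
  if (is.na(t_w))
    return(list(t_next = NA_real_, t_next_mod = NA_real_,
                days_elapsed = NA_integer_, t_wake = NA_real_,
                regime = "no_wake"))
  H1 <- lower_threshold(t_w, p)
  f_w <- function(s) h_wake(s, t_w, H1, p) - upper_threshold(s, p)
  t_n <- find_crossing(f_w, t_w, t_w + 24 * max_days, dir = 1, step = scan_step)
  if (is.na(t_n))
    return(list(t_next = NA_real_, t_next_mod = NA_real_,
                days_elapsed = NA_integer_, t_wake = t_w, regime = "no_sleep"))
  list(t_next = t_n, t_next_mod = t_n %% 24,
       days_elapsed = as.integer(floor((t_n - t_onset) / 24)),
       t_wake = t_w, regime = "ok")
}

#' First-return map of sleep-onset times
#'
#' Tabulates the map sending a sleep-onset time (modulo 24 h, half-open
#' \code{[0, 24)}) to the next sleep-onset time, locates its discontinuities
#' (where neighbouring onsets lead to trajectories on opposite sides of a
#' threshold tangency) and its fixed points. Discontinuities are detected as
#' jumps exceeding \code{jump_threshold} between adjacent grid values and
#' refined by bisection; fixed points are located by a sign change of
#' \eqn{map(t) - t} (mod 24) and refined by root-finding on the exact map,
#' with the local slope estimated by central differences.
#'
#' @param p \code{\link{two_process_params}}.
#' @param n_grid Number of grid points on \code{[0, 24)} (at least 48).
#' @param jump_threshold Jump (hours) flagging a candidate discontinuity.
#' @param refine_tol Bisection tolerance (hours) for discontinuity locations.
#' @param slope_h Central-difference step (hours) for fixed-point slopes.
#' @return Object of class \code{return_map}: list with \code{grid} (data
#'   frame \code{t_onset, t_next, days_elapsed, regime}),
#'   \code{discontinuities} (data frame \code{location, left, right,
#'   jump}), \code{fixed_points} (data frame \code{t_star, slope, stable})
#'   and \code{params}.
#' @export
build_return_map <- function(p, n_grid = 96, jump_threshold = 0.5,
                             refine_tol = 1e-4, slope_h = 1e-3) {
  stopifnot(inherits(p, "two_process_params"), n_grid >= 48)
  tg <- seq(0, 24, length.out = n_grid + 1L)[seq_len(n_grid)]
  res <- lapply(tg, function(t) next_onset(p, t))
  vals <- vapply(res, function(r) r$t_next_mod, numeric(1))
  days <- vapply(res, function(r) as.numeric(r$days_elapsed), numeric(1))
  regime <- vapply(res, function(r) r$regime, character(1))
  grid <- data.frame(t_onset = tg, t_next = vals, days_elapsed = days,
                     regime = regime, stringsAsFactors = FALSE)

  map_mod <- function(t) next_onset(p, t)$t_next_mod
  # candidate discontinuities between consecutive grid points (circular)
  discs <- list()
  if (all(regime == "ok")) {
    i2 <- c(seq_len(n_grid - 1L) + 1L, 1L)
    t_right <- c(tg[-1L], tg[1L] + 24)
    for (i in seq_len(n_grid)) {
      vL <- vals[i]; vR <- vals[i2[i]]
      if (abs(circ_diff(vR, vL)) <= jump_threshold) next
      lo <- tg[i]; hi <- t_right[i]; fL <- vL; fR <- vR
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        fm <- map_mod(mid %% 24)
        if (abs(circ_diff(fm, fL)) < abs(circ_diff(fm, fR))) {
          lo <- mid; fL <- fm
        } else {
          hi <- mid; fR <- fm
        }
      }
      # keep only genuine jumps (a smooth steep stretch refines to nothing)
      if (abs(circ_diff(fR, fL)) >= jump_threshold)
        discs[[length(discs) + 1L]] <-
          data.frame(location = ((lo + hi) / 2) %% 24, left = fL, right = fR,
                     jump = circ_diff(fR, fL))
    }
  }
  discs <- if (length(discs)) do.call(rbind, discs) else
    data.frame(location = numeric(0), left = numeric(0), right = numeric(0),
               jump = numeric(0))

  # fixed points: sign change of g(t) = circ_diff(map(t), t) between adjacent
  # grid points not separated by a discontinuity
  fps <- list()
  if (all(regime == "ok")) {
    g_vals <- circ_diff(vals, tg)
    i2 <- c(seq_len(n_grid - 1L) + 1L, 1L)
    t_right <- c(tg[-1L], tg[1L] + 24)
    for (i in seq_len(n_grid)) {
      gL <- g_vals[i]; gR <- circ_diff(vals[i2[i]], t_right[i])
      if (!is.finite(gL) || !is.finite(gR) || gL * gR > 0) next
      if (any(discs$location > tg[i] & discs$location < t_right[i])) next
      root <- tryCatch(
        uniroot(function(t) circ_diff(map_mod(t %% 24), t %% 24),
                c(tg[i], t_right[i]), tol = 1e-8)$root %% 24,
        error = function(e) NA_real_)
      if (is.na(root)) next
      # discard antipodal wrap artefacts (map - t crossing +/- 12 h)
      if (abs(circ_diff(map_mod(root), root)) > 1e-4) next
      sl <- circ_diff(map_mod((root + slope_h) %% 24),
                      map_mod((root - slope_h) %% 24)) / (2 * slope_h)
      fps[[length(fps) + 1L]] <-
        data.frame(t_star = root, slope = sl, stable = abs(sl) < 1)
    }
  }
  fps <- if (length(fps)) do.call(rbind, fps) else
    data.frame(t_star = numeric(0), slope = numeric(0), stable = logical(0))

  structure(list(grid = grid, discontinuities = discs, fixed_points = fps,
                 params = p),
            class = "return_map")
}

#' @export
print.return_map <- function(x, ...) {
  cat(sprintf("First-return map: %d grid points, %d discontinuity(ies), %d fixed point(s)\n",
              nrow(x$grid), nrow(x$discontinuities), nrow(x$fixed_points)))
  if (nrow(x$fixed_points))
    cat(sprintf("  fixed point at %.3f h (mod 24), slope %.3f\n",
                x$fixed_points$t_star[1L], x$fixed_points$slope[1L]))
  invisible(x)
}

#' Interpolate a tabulated return map
#'
#' Piecewise-linear interpolation of the tabulated map within the smooth
#' segments between refined discontinuities; queries inside the
#' grid interval that brackets a discontinuity take the value of the nearer
#' side.
#'
#' @param rm A \code{\link{build_return_map}} result.
#' @param t Onset times (hours, any real; reduced mod 24).
#' @return Interpolated next-onset times (mod 24).
#' @export
predict_return_map <- function(rm, t) {
  tg <- rm$grid$t_onset; vals <- rm$grid$t_next
  n <- length(tg)
  vapply(t %% 24, function(ti) {
    i <- findInterval(ti, tg)
    if (i < 1L) i <- n
    j <- if (i == n) 1L else i + 1L
    tL <- tg[i]; tR <- if (i == n) tg[1L] + 24 else tg[j]
    d_in <- rm$discontinuities$location
    if (any(d_in > tL & d_in < tR)) {
      if (ti - tL < tR - ti) vals[i] else vals[j]
    } else {
      w <- (ti - tL) / (tR - tL)
      (vals[i] + w * circ_diff(vals[j], vals[i])) %% 24
    }
  }, numeric(1))
}

#' Iterate the sleep-onset return map
#'
#' Applies \code{\link{next_onset}} repeatedly (exact propagation, not
#' interpolation) and flags convergence when three consecutive onsets agree
#' modulo 24 h within \code{tol}.
#'
#' @param p \code{\link{two_process_params}}.
#' @param t0 Initial onset time (hours).
#' @param n Number of iterations (at least 1).
#' @param tol Convergence tolerance (hours).
#' @return Object of class \code{onset_sequence}: data frame
#'   \code{iter, t_onset, t_onset_mod, days_elapsed} with attributes
#'   \code{converged}, \code{limit} (the converged onset mod 24, or
#'   \code{NA}) and \code{regime}.
#' @export
iterate_map <- function(p, t0, n = 20, tol = 1e-3) {
  stopifnot(n >= 1)
  t_abs <- t0
  rows <- data.frame(iter = 0L, t_onset = t0, t_onset_mod = t0 %% 24,
                     days_elapsed = NA_integer_)
  regime <- "ok"
  for (k in seq_len(n)) {
    nx <- next_onset(p, t_abs)
    if (nx$regime != "ok") { regime <- nx$regime; break }
    rows <- rbind(rows, data.frame(iter = k, t_onset = nx$t_next,
                                   t_onset_mod = nx$t_next_mod,
                                   days_elapsed = nx$days_elapsed))
    t_abs <- nx$t_next
  }
  mods <- rows$t_onset_mod
  converged <- FALSE; limit <- NA_real_; conv_iter <- NA_integer_
  if (length(mods) >= 3L) {
    d <- abs(circ_diff(mods[-1L], mods[-length(mods)]))
    ok <- d < tol
    run <- which(ok & c(ok[-1L], FALSE))    # two consecutive small steps
    if (length(run)) {
      converged <- TRUE
      conv_iter <- rows$iter[run[1L] + 2L]
      limit <- mods[run[1L] + 2L]
    }
  }
  structure(rows, class = c("onset_sequence", "data.frame"),
            converged = converged, limit = limit, conv_iter = conv_iter,
            regime = regime)
}

# minimum interior distance between the trajectory and the thresholds over a
# map step starting at onset t0; used for tangency certificates at
# discontinuities.  Returns the smallest positive near-miss (Inf if the
# trajectory has no interior local minimum of distance).
tangency_distance <- function(p, t0, scan_step = 0.002, edge = 0.05) {
  nx <- next_onset(p, t0)
  if (nx$regime != "ok") return(Inf)
  H_on <- upper_threshold(t0, p)
  H_wk <- lower_threshold(nx$t_wake, p)
  best <- Inf
  episode_min <- function(f, a, b) {
    if (b - a < 3 * edge) return(Inf)
    tt <- seq(a + edge, b - edge, by = scan_step)
    d <- f(tt)
    i <- which(d[-c(1L, length(d))] < d[-c(length(d) - 1L, length(d))] &
                 d[-c(1L, length(d))] < d[-(1:2)]) + 1L
    if (!length(i)) return(Inf)
    mins <- vapply(i, function(j)
      stats::optimize(f, c(tt[j - 1L], tt[j + 1L]))$objective, numeric(1))
    min(mins)
  }
  # during sleep the near-miss is to the lower threshold from above
  best <- min(best, episode_min(function(s)
    h_sleep(s, t0, H_on, p) - lower_threshold(s, p), t0, nx$t_wake))
  # during wake the near-miss is to the upper threshold from below
  best <- min(best, episode_min(function(s)
    upper_threshold(s, p) - h_wake(s, nx$t_wake, H_wk, p),
    nx$t_wake, nx$t_next))
  best
}
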