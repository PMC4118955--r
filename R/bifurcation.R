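# ---- parameter scans and grazing-bifurcation location -----------------------

# apply a scan parameter to a parameter object
apply_scan_param <- function(p, param, value) {
  if (inherits(p, "two_process_params")) {
    switch(param,
      chi = { p$chi_w <- value; p$chi_s <- value; p },
      threshold_shift = {
        p$H0_plus <- p$H0_plus + value
        p$H0_minus <- p$H0_minus + value
        p
      },
      stop(sprintf("apply_scan_param: parameter '%s' is not scannable for the two-process model",
                   param), call. = FALSE))
  } else if (inherits(p, "pr_params")) {
    switch(param,
      chi = { p$chi <- value; p },
      mean_vlpo_drive = { p$D0_v <- value; p },
      stop(sprintf("apply_scan_param: parameter '%s' is not scannable for the PR model",
                   param), call. = FALSE))
  } else stop("apply_scan_param: unsupported parameter object", call. = FALSE)
}

# converged pattern summary at one parameter value, optionally warm-started
converged_summary <- function(p, transient_days, max_period,
                              warm = NULL, dt_out = 0.02) {
  span <- 24 * (transient_days + 2 * max_period)
  if (inherits(p, "two_process_params")) {
    H0 <- if (is.null(warm)) NULL else warm$H
    st <- if (is.null(warm)) "wake" else warm$state
    t0 <- if (is.null(warm)) 0 else warm$t %% 24
    sim <- simulate_two_process(p, t_span = span, H_init = H0, state_init = st,
                                t_start = t0, dt_out = 1)  # coarse ts; events are exact
    warm_out <- list(H = sim$core$H_final, state = sim$core$state_final,
                     t = sim$core$t_final)
  } else {
    y0 <- if (is.null(warm)) "wake" else warm$y
    t0 <- if (is.null(warm)) 0 else warm$t %% 24
    sim <- simulate_pr(p, t_span = span, init = y0, t_start = t0, dt_out = dt_out)
    last <- sim$timeseries[nrow(sim$timeseries), ]
    warm_out <- list(y = c(last$V_v, last$V_m, last$H), t = last$time_h)
  }
  list(summary = classify_pattern(sim$pattern, max_period = max_period),
       sim = sim, warm = warm_out)
}

#' Scan a parameter and classify the resulting sleep-wake patterns
#'
#' Simulates the model to its attractor at each grid value (discarding a
#' transient, warm-starting each point from the previous one) and classifies
#' the converged pattern. Supported axes: the homeostatic time constant
#' \code{"chi"} (both models; for the two-process model the wake and sleep
#' constants move together), \code{"threshold_shift"} (two-process: both
#' thresholds moved by the same amount, leaving their distance unchanged) and
#' \code{"mean_vlpo_drive"} (PR: the constant VLPO drive component
#' \code{D0_v}, the drive-side equivalent of a threshold shift).
#'
#' @param p Base parameter object (\code{two_process_params} or
#'   \code{pr_params}).
#' @param param Scan axis name (see above).
#' @param values Strictly monotone numeric grid.
#' @param transient_days Discarded transient per grid point (default 30).
#' @param max_period Largest period (days) tested for; the per-point
#'   simulation covers \code{transient_days + 2 * max_period} days.
#' @param recalibrate For \code{chi} scans of a two-process model derived
#'   from the mutual-inhibition model: re-run the asymptote calibration from
#'   \code{source_pr} at every grid value instead of holding the asymptotes
#'   fixed at their default-point values. The fixed-asymptote policy is the
#'   default (it mirrors how the equivalence is normally used, at the cost of
#'   a known shift in the bifurcation locations); per-point recalibration is
#'   a sensitivity study and is substantially slower.
#' @param source_pr The sigmoid \code{\link{pr_params}} the two-process set
#'   was derived from (required when \code{recalibrate = TRUE}).
#' @return Object of class \code{bifurcation_scan}: list with \code{summary}
#'   (data frame \code{value, episodes_per_day, period_days, daily_sleep_h,
#'   converged, regime}), \code{intervals} (per-value data frames of sleep
#'   intervals of the final window, folded mod 24 with onsets assigned to the
#'   day of their start), \code{critical} (data frame of bracketing values
#'   where the episode count or regime changes, with a type column), and the
#'   scan metadata.
#' @export
scan_parameter <- function(p, param, values, transient_days = 30,
                           max_period = 16, recalibrate = FALSE,
                           source_pr = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (!(all(diff(values) > 0) || all(diff(values) < 0)))
    stop("scan_parameter: 'values' must be strictly monotone", call. = FALSE)
  if (recalibrate &&
      !(inherits(p, "two_process_params") && inherits(source_pr, "pr_params") &&
          identical(param, "chi")))
    stop("scan_parameter: 'recalibrate' applies to chi scans of a ",
         "two-process model with 'source_pr' supplied", call. = FALSE)
  warm <- NULL
  rows <- list(); rasters <- list()
  for (i in seq_along(values)) {
    pi_ <- if (recalibrate) {
      cal <- tryCatch(calibrate_switch_from_pr(
        apply_scan_param(source_pr, "chi", values[i]), report = FALSE),
        error = function(e) NULL)
      if (is.null(cal)) apply_scan_param(p, param, values[i])
      else cal$two_process
    } else apply_scan_param(p, param, values[i])
    res <- tryCatch(
      converged_summary(pi_, transient_days, max_period, warm = warm),
      error = function(e) NULL)
    if (is.null(res)) {
      rows[[i]] <- data.frame(value = values[i], episodes_per_day = NA_real_,
                              period_days = NA_real_, daily_sleep_h = NA_real_,
                              converged = FALSE, regime = "error")
      rasters[[i]] <- data.frame(day = integer(0), onset_h = numeric(0),
                                 offset_h = numeric(0))
      next
    }
    s <- res$summary
    warm <- res$warm
    rows[[i]] <- data.frame(value = values[i],
                            episodes_per_day = s$episodes_per_day,
                            period_days = s$period_days,
                            daily_sleep_h = s$daily_sleep_h,
                            converged = s$converged, regime = s$regime)
    si <- pattern_sleep_intervals(res$sim$pattern)
    t_end <- res$sim$pattern$t_end
    keep <- si[, 1L] > t_end - 24 * 2 * max_period
    si <- si[keep, , drop = FALSE]
    rasters[[i]] <- if (nrow(si)) {
      day <- floor(si[, 1L] / 24)
      data.frame(day = as.integer(day - min(day)),
                 onset_h = si[, 1L] %% 24,
                 offset_h = si[, 1L] %% 24 + (si[, 2L] - si[, 1L]))
    } else data.frame(day = integer(0), onset_h = numeric(0),
                      offset_h = numeric(0))
  }
  summary <- do.call(rbind, rows)
  # critical brackets where the classified pattern changes
  crit <- list()
  for (i in seq_len(nrow(summary) - 1L)) {
    a <- summary[i, ]; b <- summary[i + 1L, ]
    type <- NULL
    if (a$regime == "cycling" && b$regime == "no_sleep") type <- "no-sleep boundary"
    else if (a$regime == "cycling" && b$regime == "no_wake") type <- "no-wake boundary"
    else if (a$regime == "no_sleep" && b$regime == "cycling") type <- "no-sleep boundary"
    else if (a$regime == "no_wake" && b$regime == "cycling") type <- "no-wake boundary"
    else if (a$regime == "cycling" && b$regime == "cycling" &&
             isTRUE(a$converged) && isTRUE(b$converged) &&
             !isTRUE(all.equal(a$episodes_per_day, b$episodes_per_day)))
      type <- "episode-adding"
    if (!is.null(type))
      crit[[length(crit) + 1L]] <- data.frame(lower = min(a$value, b$value),
                                              upper = max(a$value, b$value),
                                              type = type)
  }
  crit <- if (length(crit)) do.call(rbind, crit) else
    data.frame(lower = numeric(0), upper = numeric(0), type = character(0))
  structure(list(param = param, summary = summary, intervals = rasters,
                 critical = crit, base_params = p),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("Bifurcation scan over '%s' (%d values)\n", x$param, nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Locate a grazing (episode-adding) bifurcation
#'
#' Bisects on the classified episode count between two parameter values with
#' different converged patterns. At the returned critical value the
#' trajectory becomes tangent to a switching threshold: the certificate
#' reports the minimum interior distance between the converged trajectory and
#' the grazed threshold, the trajectory-minus-threshold time derivative at the
#' near-touch (both should vanish at a tangency), and -- for the two-process
#' model -- the distance of the return-map discontinuity's nearer one-sided
#' limit from the diagonal (a grazing bifurcation occurs when the map
#' discontinuity crosses the diagonal).
#'
#' @param p Base parameter object.
#' @param param Scan axis (as in \code{\link{scan_parameter}}).
#' @param bracket Length-2 numeric; the endpoints must exhibit different
#'   episode counts (checked; equal counts are an error).
#' @param param_tol Bisection tolerance on the parameter.
#' @param transient_days,max_period Convergence protocol per evaluation.
#' @param certify Compute the tangency certificate (two-process only for the
#'   map part).
#' @return List of class \code{grazing_point}: \code{critical} (parameter
#'   value), \code{episodes} (episode counts on the two sides),
#'   \code{certificate} (list \code{min_distance}, \code{tangency_slope},
#'   \code{map_diag_gap_h}) when requested.
#' @export
locate_grazing <- function(p, param, bracket, param_tol = 1e-3,
                           transient_days = 30, max_period = 8,
                           certify = TRUE) {
  stopifnot(length(bracket) == 2L)
  ep <- function(v) {
    pi_ <- apply_scan_param(p, param, v)
    converged_summary(pi_, transient_days, max_period)$summary$episodes_per_day
  }
  e_lo <- ep(bracket[1L]); e_hi <- ep(bracket[2L])
  if (isTRUE(all.equal(e_lo, e_hi)))
    stop("locate_grazing: bracket endpoints have equal episode counts", call. = FALSE)
  lo <- bracket[1L]; hi <- bracket[2L]
  while (abs(hi - lo) > param_tol) {
    mid <- (lo + hi) / 2
    e_mid <- ep(mid)
    if (isTRUE(all.equal(e_mid, e_lo))) lo <- mid else { hi <- mid; e_hi <- e_mid }
  }
  critical <- (lo + hi) / 2
  out <- list(critical = critical, episodes = c(lower = e_lo, upper = e_hi),
              param = param, bracket = bracket)
  if (certify) {
    # certify on the side that has not yet gained the extra episode: the
    # near-miss distance vanishes as the tangency is approached
    side <- if (e_lo <= e_hi) lo else hi
    pc <- apply_scan_param(p, param, side)
    out$certificate <- grazing_certificate(pc, transient_days = transient_days)
  }
  class(out) <- "grazing_point"
  out
}

# tangency certificate at (or extremely near) a grazing parameter value
grazing_certificate <- function(p, transient_days = 30, days = 6) {
  if (inherits(p, "two_process_params")) {
    sim <- simulate_two_process(p, t_span = 24 * (transient_days + days),
                                dt_out = 1)
    ons <- pattern_onsets(sim$pattern)
    ons <- ons[ons > 24 * transient_days]
    if (!length(ons)) return(list(min_distance = NA_real_,
                                  tangency_slope = NA_real_,
                                  map_diag_gap_h = NA_real_))
    dists <- vapply(ons, function(t0) tangency_distance(p, t0), numeric(1))
    dmin <- min(dists)
    # derivative of (H - threshold) at the near-touch point of the closest pass
    t0 <- ons[which.min(dists)]
    slope <- tangency_slope_at(p, t0)
    rmap <- build_return_map(p, n_grid = 64)
    gap <- if (nrow(rmap$discontinuities)) {
      d <- rmap$discontinuities
      min(pmin(abs(circ_diff(d$left, d$location)),
               abs(circ_diff(d$right, d$location))))
    } else NA_real_
    list(min_distance = dmin, tangency_slope = slope, map_diag_gap_h = gap)
  } else {
    # PR model: certify on the drive scale against the fold drives
    fp <- fold_points(p, p$A)
    sim <- simulate_pr(p, t_span = 24 * (transient_days + days), dt_out = 0.01)
    ts <- sim$timeseries
    tail <- ts[ts$time_h > 24 * transient_days, ]
    Dv <- vlpo_drive(tail$time_h, tail$H, p)
    wake <- tail$state == "wake"
    d <- max(fp$D_v) - Dv[wake]
    # smallest positive interior near-miss to the wake-loss fold
    pos <- d[d > 0]
    list(min_distance = if (length(pos)) min(pos) else NA_real_,
         tangency_slope = NA_real_, map_diag_gap_h = NA_real_)
  }
}

# d/dt (H - threshold) at the interior near-touch point of the map step from t0
tangency_slope_at <- function(p, t0, scan_step = 0.002, edge = 0.05) {
  nx <- next_onset(p, t0)
  if (nx$regime != "ok") return(NA_real_)
  H_on <- upper_threshold(t0, p)
  H_wk <- lower_threshold(nx$t_wake, p)
  best <- c(Inf, NA_real_)
  consider <- function(f, df, a, b, best) {
    if (b - a < 3 * edge) return(best)
    tt <- seq(a + edge, b - edge, by = scan_step)
    d <- f(tt)
    i <- which(d[-c(1L, length(d))] < d[-c(length(d) - 1L, length(d))] &
                 d[-c(1L, length(d))] < d[-(1:2)]) + 1L
    if (!length(i)) return(best)
    for (j in i) {
      o <- stats::optimize(f, c(tt[j - 1L], tt[j + 1L]))
      if (o$objective < best[1L]) best <- c(o$objective, df(o$minimum))
    }
    best
  }
  best <- consider(
    function(s) h_sleep(s, t0, H_on, p) - lower_threshold(s, p),
    function(s) -(h_sleep(s, t0, H_on, p) - p$lower_asymptote) / p$chi_s -
      circadian_deriv(s, p$circadian),
    t0, nx$t_wake, best)
  best <- consider(
    function(s) upper_threshold(s, p) - h_wake(s, nx$t_wake, H_wk, p),
    function(s) circadian_deriv(s, p$circadian) -
      (p$mu - h_wake(s, nx$t_wake, H_wk, p)) / p$chi_w,
    nx$t_wake, nx$t_next, best)
  best[2L]
}

#' @export
print.grazing_point <- function(x, ...) {
  cat(sprintf("Grazing bifurcation of '%s' at %.6g (episode count %.3g -> %.3g)\n",
              x$param, x$critical, x$episodes[1L], x$episodes[2L]))
  if (!is.null(x$certificate))
    cat(sprintf("  certificate: min distance %.3g, tangency slope %.3g, map-diagonal gap %.3g h\n",
                x$certificate$min_distance, x$certificate$tangency_slope,
                x$certificate$map_diag_gap_h))
  invisible(x)
}
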