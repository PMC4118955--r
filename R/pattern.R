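#' Sleep-wake transition pattern
#'
#' Ordered wake/sleep transition events from a simulation. Directions strictly
#' alternate; episodes shorter than \code{min_episode} hours (default one
#' minute) are merged into their neighbours before any statistics are
#' computed, which suppresses numerical chatter at grazing parameters.
#'
#' @param time_h Event times in hours (strictly increasing).
#' @param transition Character vector, \code{"wake_to_sleep"} or
#'   \code{"sleep_to_wake"}, alternating.
#' @param t_start,t_end Simulated interval covered by the pattern.
#' @param state_start State at \code{t_start} (\code{"wake"} or
#'   \code{"sleep"}).
#' @param truncated Logical: \code{TRUE} when the simulation ended without a
#'   further transition being found (e.g. permanent-wake or permanent-sleep
#'   regimes).
#' @param min_episode Minimum episode duration in hours; shorter episodes are
#'   merged.
#' @return Object of class \code{sleep_wake_pattern} with elements
#'   \code{events} (data frame \code{time_h}, \code{transition}),
#'   \code{t_start}, \code{t_end}, \code{state_start}, \code{truncated}.
#' @export
sleep_wake_pattern <- function(time_h, transition, t_start, t_end,
                               state_start = "wake", truncated = FALSE,
                               min_episode = 1 / 60) {
  stopifnot(length(time_h) == length(transition))
  if (length(time_h) > 1L) {
    if (any(diff(time_h) <= 0))
      stop("sleep_wake_pattern: event times must be strictly increasing", call. = FALSE)
    if (any(transition[-1L] == transition[-length(transition)]))
      stop("sleep_wake_pattern: transition directions must alternate", call. = FALSE)
  }
  # merge episodes shorter than min_episode: dropping the two transitions that
  # bound a short episode joins its neighbours
  if (length(time_h) > 1L && min_episode > 0) {
    repeat {
      d <- diff(time_h)
      j <- which(d < min_episode)
      if (!length(j)) break
      drop <- c(j[1L], j[1L] + 1L)
      time_h <- time_h[-drop]
      transition <- transition[-drop]
      if (length(time_h) < 2L) break
    }
  }
  structure(list(events = data.frame(time_h = time_h, transition = transition,
                                     stringsAsFactors = FALSE),
                 t_start = t_start, t_end = t_end,
                 state_start = state_start, truncated = truncated),
            class = "sleep_wake_pattern")
}

# wake->sleep onset times
pattern_onsets <- function(pat) {
  pat$events$time_h[pat$events$transition == "wake_to_sleep"]
}

# sleep intervals (onset, offset) as a two-column matrix, clipped to the span
pattern_sleep_intervals <- function(pat) {
  ev <- pat$events
  times <- c(pat$t_start, ev$time_h, pat$t_end)
  states <- character(nrow(ev) + 1L)
  states[1L] <- pat$state_start
  if (nrow(ev))
    states[-1L] <- ifelse(ev$transition == "wake_to_sleep", "sleep", "wake")
  i <- which(states == "sleep")
  if (!length(i)) return(matrix(numeric(0), ncol = 2))
  cbind(onset = times[i], offset = times[i + 1L])
}

#' @export
print.sleep_wake_pattern <- function(x, ...) {
  cat(sprintf("Sleep-wake pattern over [%.2f, %.2f] h: %d transitions%s\n",
              x$t_start, x$t_end, nrow(x$events),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Classify a sleep-wake pattern
#'
#' Detects the periodicity of a converged sleep-wake pattern: the period is
#' the smallest integer number of (circadian) days after which the sleep-onset
#' sequence repeats, compared modulo 24 h within \code{tol}. Episodes per day
#' and total daily sleep are then averages over one period.
#'
#' @param pat A \code{\link{sleep_wake_pattern}} (transient already
#'   discarded, i.e. from the tail of a long run).
#' @param max_period Largest period, in days, that is searched for (default
#'   16); patterns that do not repeat within this horizon are reported with
#'   \code{converged = FALSE}.
#' @param tol Time tolerance (hours) for event matching.
#' @return Object of class \code{pattern_summary}: a list with
#'   \code{episodes_per_day}, \code{period_days}, \code{daily_sleep_h},
#'   \code{converged}, and \code{regime} (\code{"cycling"}, \code{"no_sleep"}
#'   or \code{"no_wake"}).
#' @export
classify_pattern <- function(pat, max_period = 16, tol = 0.02) {
  stopifnot(inherits(pat, "sleep_wake_pattern"))
  out <- function(epd, per, dsl, conv, regime) {
    structure(list(episodes_per_day = epd, period_days = per,
                   daily_sleep_h = dsl, converged = conv, regime = regime),
              class = "pattern_summary")
  }
  ev <- pat$events
  span_days <- (pat$t_end - pat$t_start) / 24
  if (nrow(ev) == 0L) {
    regime <- if (identical(pat$state_start, "wake")) "no_sleep" else "no_wake"
    return(out(0, NA_real_, if (regime == "no_wake") 24 else 0, FALSE, regime))
  }
  t_end <- pat$t_end
  for (p in seq_len(min(max_period, floor(span_days / 2)))) {
    win <- 24 * p
    a <- ev$time_h[ev$time_h > t_end - win & ev$time_h <= t_end]
    b <- ev$time_h[ev$time_h > t_end - 2 * win & ev$time_h <= t_end - win]
    ta <- ev$transition[ev$time_h > t_end - win & ev$time_h <= t_end]
    tb <- ev$transition[ev$time_h > t_end - 2 * win & ev$time_h <= t_end - win]
    if (length(a) && length(a) == length(b) && all(ta == tb) &&
        all(abs((a - win) - b) < tol)) {
      onsets <- sum(ta == "wake_to_sleep")
      # sleep within one period window anchored at the last event, counted by
      # interval overlap so that clipped episodes are handled exactly
      t_ref <- max(ev$time_h)
      si <- pattern_sleep_intervals(pat)
      ov <- pmax(0, pmin(si[, 2L], t_ref) - pmax(si[, 1L], t_ref - win))
      dsl <- sum(ov) / p
      return(out(onsets / p, p, dsl, TRUE, "cycling"))
    }
  }
  # no events near the end: the run settled into a single state
  last_ev <- max(ev$time_h)
  if (t_end - last_ev > 24 * max_period) {
    asleep <- ev$transition[which.max(ev$time_h)] == "wake_to_sleep"
    return(out(0, NA_real_, if (asleep) 24 else 0, FALSE,
               if (asleep) "no_wake" else "no_sleep"))
  }
  # not repeating within the horizon
  si <- pattern_sleep_intervals(pat)
  win <- min(24 * max_period, pat$t_end - pat$t_start)
  ov <- pmax(0, pmin(si[, 2L], t_end) - pmax(si[, 1L], t_end - win))
  dsl <- sum(ov) / (win / 24)
  epd <- sum(ev$transition == "wake_to_sleep" & ev$time_h > t_end - win) / (win / 24)
  out(epd, NA_real_, dsl, FALSE, "cycling")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("Pattern: %s, %.3g episode(s)/day, period %s day(s), %.3g h sleep/day%s\n",
              x$regime, x$episodes_per_day,
              if (is.na(x$period_days)) "?" else format(x$period_days),
              x$daily_sleep_h,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
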