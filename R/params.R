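# package-level cache for derived default parameter sets (deterministic,
# computed once per session)
.sleepdyn_cache <- new.env(parent = emptyenv())

#' Two-process model parameters
#'
#' The two-process model describes a homeostatic sleep pressure \eqn{H} that
#' relaxes exponentially towards an upper asymptote \eqn{\mu} during wake
#' (time constant \code{chi_w}) and towards a lower asymptote (default 0)
#' during sleep (time constant \code{chi_s}). Switching occurs at
#' circadian-modulated thresholds
#' \eqn{H^\pm(t) = H_0^\pm + C(t)} where \eqn{C} is a
#' \code{\link{circadian_waveform}}: wake-to-sleep at the upper threshold,
#' sleep-to-wake at the lower threshold.
#'
#' @param mu Upper asymptote (pressure units).
#' @param H0_plus,H0_minus Mean upper and lower switching thresholds
#'   (pressure units); \code{H0_minus < H0_plus} is required.
#' @param chi_w,chi_s Wake and sleep time constants (hours), both positive.
#' @param circadian A \code{\link{circadian_waveform}} modulating both
#'   thresholds (amplitude in pressure units).
#' @param lower_asymptote Lower asymptote (pressure units, default 0).
#' @return An object of class \code{two_process_params}.
#' @details If \eqn{\mu} does not exceed the maximum of the upper threshold a
#'   warning is raised: the homeostat may then never reach the threshold and
#'   wake never ends (this is a legitimate regime -- it is how the no-sleep
#'   boundary of drive scans arises -- hence a warning, not an error).
#' @seealso \code{\link{two_process_human}} for the human-equivalent default
#'   set derived from the mutual-inhibition model.
#' @export
two_process_params <- function(mu, H0_plus, H0_minus, chi_w, chi_s,
                               circadian = circadian_waveform(0),
                               lower_asymptote = 0) {
  stopifnot(inherits(circadian, "circadian_waveform"))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("two_process_params: '%s' must be a finite number", nm), call. = FALSE)
    x
  }
  mu <- num1(mu, "mu"); H0_plus <- num1(H0_plus, "H0_plus")
  H0_minus <- num1(H0_minus, "H0_minus")
  chi_w <- num1(chi_w, "chi_w"); chi_s <- num1(chi_s, "chi_s")
  lower_asymptote <- num1(lower_asymptote, "lower_asymptote")
  if (chi_w <= 0) stop("two_process_params: 'chi_w' must be > 0", call. = FALSE)
  if (chi_s <= 0) stop("two_process_params: 'chi_s' must be > 0", call. = FALSE)
  if (H0_minus >= H0_plus)
    stop("two_process_params: 'H0_minus' must be below 'H0_plus'", call. = FALSE)
  amax <- abs(circadian$amplitude) * sum(abs(circadian$harmonics))
  if (mu <= H0_plus + amax)
    warning("two_process_params: 'mu' does not exceed the maximum upper threshold; ",
            "wake may never end", call. = FALSE)
  structure(list(mu = mu, H0_plus = H0_plus, H0_minus = H0_minus,
                 chi_w = chi_w, chi_s = chi_s, circadian = circadian,
                 lower_asymptote = lower_asymptote),
            class = "two_process_params")
}

#' Mutual-inhibition (Phillips-Robinson) model parameters
#'
#' Parameters of the sleep-wake flip-flop: mutually inhibitory
#' ventro-lateral pre-optic (VLPO, sleep-active) and mono-aminergic
#' (MA, wake-active) populations driven by homeostatic and circadian
#' processes,
#' \deqn{\tau \dot V_v = -V_v - \nu_{vm} Q(V_m) + D_v(t), \quad
#'       \tau \dot V_m = -V_m - \nu_{mv} Q(V_v) + A,}
#' \deqn{\chi \dot H = P(Q(V_m)) - H, \quad
#'       D_v(t) = \nu_{vh} H + D_{0v} + C(t),}
#' with the sigmoid \eqn{Q} of \code{\link{firing_rate}}. All weights are
#' defined positive and enter with explicit signs. The production term is
#' either linear, \eqn{P(Q) = \mu_h Q} (the original formulation), or
#' saturating, \eqn{P(Q) = \mu_{sat} Q/(Q + Q_{half})}, which caps the
#' production rate at high firing; the choice is controlled by
#' \code{asymptote_form}.
#'
#' @param Q_max Maximum firing rate (1/s).
#' @param theta Mean firing threshold (mV).
#' @param sigma Sigmoid width (mV).
#' @param nu_vm Inhibitory weight VLPO <- MA (mV s).
#' @param nu_mv Inhibitory weight MA <- VLPO (mV s).
#' @param nu_vh Homeostatic drive weight (mV per pressure unit).
#' @param D0_v Constant component of the VLPO drive, including the mean
#'   circadian component (mV; negative for the human default set).
#' @param A Constant drive to the MA (mV).
#' @param chi Homeostatic time constant (hours).
#' @param mu_h Homeostatic production gain (pressure s).
#' @param tau Neuronal relaxation time (seconds; converted internally).
#' @param circadian \code{\link{circadian_waveform}} for the oscillatory part
#'   of the VLPO drive (mV).
#' @param asymptote_form \code{"linear"} or \code{"saturating"}.
#' @param Q_half Half-saturation rate of the saturating production form (1/s).
#' @param mu_sat Scale of the saturating form (pressure units). Default
#'   \code{NULL} normalises it so that the saturating and linear forms agree
#'   at the unopposed waking rate \eqn{Q(A)}.
#' @return Object of class \code{pr_params}.
#' @details The model assumes a strong separation between the neuronal
#'   timescale \eqn{\tau} (seconds) and the homeostatic timescale \eqn{\chi}
#'   (hours); a warning is issued if \eqn{\tau/\chi > 10^{-2}}.
#' @seealso \code{\link{pr_human}} for the canonical human parameter set.
#' @export
pr_params <- function(Q_max = 100, theta = 10, sigma = 3,
                      nu_vm = 2.1, nu_mv = 1.8, nu_vh = 1.0,
                      D0_v = -13.05, A = 1.3, chi = 45, mu_h = 4.4, tau = 10,
                      circadian = circadian_waveform(2.9),
                      asymptote_form = c("linear", "saturating"),
                      Q_half = 1, mu_sat = NULL) {
  asymptote_form <- match.arg(asymptote_form)
  stopifnot(inherits(circadian, "circadian_waveform"))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("pr_params: '%s' must be a finite number", nm), call. = FALSE)
    x
  }
  for (nm in c("Q_max", "theta", "sigma", "nu_vm", "nu_mv", "nu_vh", "D0_v",
               "A", "chi", "mu_h", "tau", "Q_half"))
    assign(nm, num1(get(nm), nm))
  for (nm in c("Q_max", "sigma", "tau", "chi", "mu_h"))
    if (get(nm) <= 0)
      stop(sprintf("pr_params: '%s' must be > 0", nm), call. = FALSE)
  if (tau / (chi * 3600) > 1e-2)
    warning("pr_params: timescale separation tau/chi above 1e-2; ",
            "the slow-manifold description may be inaccurate", call. = FALSE)
  p <- structure(list(Q_max = Q_max, theta = theta, sigma = sigma,
                      nu_vm = nu_vm, nu_mv = nu_mv, nu_vh = nu_vh,
                      D0_v = D0_v, A = A, chi = chi, mu_h = mu_h, tau = tau,
                      circadian = circadian, asymptote_form = asymptote_form,
                      Q_half = Q_half, mu_sat = NA_real_),
                 class = "pr_params")
  p$mu_sat <- if (is.null(mu_sat)) {
    qa <- firing_rate(A, p)          # unopposed waking rate
    mu_h * (qa + Q_half)             # so that P_sat(qa) == mu_h * qa
  } else num1(mu_sat, "mu_sat")
  p
}

#' Hard-switch variant of the mutual-inhibition model
#'
#' Same structure as \code{\link{pr_params}} but with the sigmoid firing
#' function replaced by the hard switch of \code{\link{firing_switch}}:
#' a population fires at \code{Q_bar} when its potential exceeds
#' \code{V_th} and is silent otherwise. On the slow manifold this variant maps
#' exactly onto the two-process model (see
#' \code{\link{pr_switch_to_two_process}}).
#'
#' @param ... Fields of \code{\link{pr_params}}.
#' @param Q_bar Switch-on firing rate (1/s), \code{0 < Q_bar <= Q_max}. Should
#'   be close to the mean population rate during wake, far below
#'   \code{Q_max}; a warning is raised when it exceeds half of \code{Q_max}.
#' @param V_th Switch voltage (mV). Must lie below \code{A}, otherwise the MA
#'   can never switch on and no sleep-wake cycling occurs (an error).
#' @return Object of class \code{pr_switch_params} (inherits
#'   \code{pr_params}).
#' @export
pr_switch_params <- function(..., Q_bar, V_th) {
  p <- pr_params(...)
  if (!is.numeric(Q_bar) || Q_bar <= 0 || Q_bar > p$Q_max)
    stop("pr_switch_params: 'Q_bar' must satisfy 0 < Q_bar <= Q_max", call. = FALSE)
  if (Q_bar > 0.5 * p$Q_max)
    warning("pr_switch_params: 'Q_bar' is not far below 'Q_max'; the switch ",
            "is meant to fire at the mean population rate", call. = FALSE)
  if (!is.numeric(V_th) || length(V_th) != 1L || !is.finite(V_th))
    stop("pr_switch_params: 'V_th' must be a finite number", call. = FALSE)
  if (p$A <= V_th)
    stop("pr_switch_params: 'A' must exceed 'V_th', otherwise the MA never ",
         "switches on and no switching occurs", call. = FALSE)
  p$Q_bar <- Q_bar
  p$V_th <- V_th
  class(p) <- c("pr_switch_params", class(p))
  p
}

#' Canonical human parameter set for the mutual-inhibition model
#'
#' The standard values of Phillips & Robinson (2007) for the human sleep-wake
#' cycle, in the all-positive sign convention: the mean circadian component of
#' the VLPO drive is folded into \code{D0_v = -13.05} mV and the oscillatory
#' part has amplitude 2.9 mV. These values produce a monophasic cycle of
#' period 24 h with roughly 8.5 h of sleep per day.
#'
#' @param ... Overrides passed on to \code{\link{pr_params}}.
#' @return A \code{pr_params} object.
#' @references Phillips AJK, Robinson PA (2007) A quantitative model of
#'   sleep-wake dynamics based on the physiology of the brainstem ascending
#'   arousal system. J Biol Rhythms 22:167-179.
#' @export
pr_human <- function(...) pr_params(...)

#' Human-equivalent two-process parameter set
#'
#' The two-process parameter set equivalent to the canonical mutual-inhibition
#' human model, obtained by running the full calibration
#' (\code{\link{calibrate_switch_from_pr}}) on \code{\link{pr_human}}:
#' thresholds from the saddle-node drives of the slow manifold, upper
#' asymptote from the homeostat extrema of one converged cycle, equal wake and
#' sleep time constants \eqn{\chi_w = \chi_s = \chi}, lower asymptote 0.
#' The result is cached for the session; it is deterministic.
#'
#' @return A \code{two_process_params} object.
#' @export
two_process_human <- function() {
  human_calibration()$two_process
}

#' Calibrated hard-switch human parameter set
#'
#' The \code{\link{pr_switch_params}} equivalent of \code{\link{pr_human}},
#' from the same cached calibration as \code{\link{two_process_human}}.
#'
#' @return A \code{pr_switch_params} object.
#' @export
pr_switch_human <- function() {
  human_calibration()$switch
}

# cached calibration of the canonical human set (deterministic)
human_calibration <- function() {
  if (is.null(.sleepdyn_cache$calibration_human))
    .sleepdyn_cache$calibration_human <- calibrate_switch_from_pr(pr_human(),
                                                                  report = FALSE)
  .sleepdyn_cache$calibration_human
}

#' @export
print.two_process_params <- function(x, ...) {
  cat("Two-process model parameters\n")
  cat(sprintf("  mu = %.4g, H0+ = %.4g, H0- = %.4g (pressure)\n",
              x$mu, x$H0_plus, x$H0_minus))
  cat(sprintf("  chi_w = %.4g h, chi_s = %.4g h, lower asymptote = %.4g\n",
              x$chi_w, x$chi_s, x$lower_asymptote))
  cat(sprintf("  circadian amplitude = %.4g, period = %.4g h\n",
              x$circadian$amplitude, 2 * pi / x$circadian$omega))
  invisible(x)
}

#' @export
print.pr_params <- function(x, ...) {
  sw <- inherits(x, "pr_switch_params")
  cat(sprintf("Mutual-inhibition (PR%s) model parameters\n", if (sw) " switch" else ""))
  cat(sprintf("  Q_max = %.4g /s, theta = %.4g mV, sigma = %.4g mV\n",
              x$Q_max, x$theta, x$sigma))
  cat(sprintf("  nu_vm = %.4g, nu_mv = %.4g mV s, nu_vh = %.4g mV/pressure\n",
              x$nu_vm, x$nu_mv, x$nu_vh))
  cat(sprintf("  D0_v = %.4g mV, A = %.4g mV, circadian amplitude = %.4g mV\n",
              x$D0_v, x$A, x$circadian$amplitude))
  cat(sprintf("  chi = %.4g h, mu_h = %.4g pressure s, tau = %.4g s, asymptote: %s\n",
              x$chi, x$mu_h, x$tau, x$asymptote_form))
  if (sw) cat(sprintf("  Q_bar = %.4g /s, V_th = %.4g mV\n", x$Q_bar, x$V_th))
  invisible(x)
}

# threshold helpers (two-process)
upper_threshold <- function(t, p) p$H0_plus + circadian_value(t, p$circadian)
lower_threshold <- function(t, p) p$H0_minus + circadian_value(t, p$circadian)

# VLPO drive (pr model)
vlpo_drive <- function(t, H, p) p$nu_vh * H + p$D0_v + circadian_value(t, p$circadian)

# homeostatic production P(Q)
h_production <- function(Q, p) {
  if (identical(p$asymptote_form, "saturating"))
    p$mu_sat * Q / (Q + p$Q_half)
  else
    p$mu_h * Q
}
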