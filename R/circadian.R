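#' Circadian waveform
#'
#' A periodic drive of the form \eqn{a \sum_k c_k \sin(k(\omega t + \alpha))},
#' used both for the threshold modulation of the two-process model and for the
#' circadian component of the VLPO drive in the mutual-inhibition model. The
#' simplest (and default) case is a pure sinusoid; higher harmonics, as used by
#' Borbely and Achermann for skewed threshold shapes, are supported through the
#' \code{harmonics} coefficient vector.
#'
#' @param amplitude Peak amplitude \eqn{a}. Units are those of the quantity the
#'   waveform modulates (pressure units for two-process thresholds, mV for the
#'   VLPO drive). May be negative, which flips the sign of the waveform; this
#'   is used when translating drive-side modulation into threshold-side
#'   modulation.
#' @param period Period in hours (default 24). The angular frequency is
#'   \eqn{\omega = 2\pi/\mathrm{period}}.
#' @param phase Phase \eqn{\alpha} in radians.
#' @param harmonics Numeric vector of harmonic coefficients \eqn{c_k}; the
#'   first entry is the fundamental and must equal 1 (unless the amplitude is
#'   zero).
#' @return An object of class \code{circadian_waveform}.
#' @examples
#' w <- circadian_waveform(1)
#' circadian_value(6, w)   # peak of the fundamental: 1
#' @export
circadian_waveform <- function(amplitude, period = 24, phase = 0, harmonics = 1) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude))
    stop("circadian_waveform: 'amplitude' must be a finite number", call. = FALSE)
  if (!is.numeric(period) || period <= 0)
    stop("circadian_waveform: 'period' must be > 0", call. = FALSE)
  if (length(harmonics) < 1L || any(!is.finite(harmonics)))
    stop("circadian_waveform: 'harmonics' must be a finite numeric vector", call. = FALSE)
  if (amplitude != 0 && abs(harmonics[1L] - 1) > 1e-12)
    stop("circadian_waveform: first entry of 'harmonics' (the fundamental) must be 1",
         call. = FALSE)
  structure(
    list(amplitude = amplitude, omega = 2 * pi / period, phase = phase,
         harmonics = as.numeric(harmonics)),
    class = "circadian_waveform"
  )
}

#' Evaluate a circadian waveform
#'
#' @param t Time in hours (vectorised).
#' @param w A \code{\link{circadian_waveform}}.
#' @return Waveform value(s) at \code{t}; identically zero when the amplitude
#'   is zero, periodic with period \eqn{2\pi/\omega}.
#' @export
circadian_value <- function(t, w) {
  stopifnot(inherits(w, "circadian_waveform"))
  if (w$amplitude == 0) return(rep(0, length(t)))
  th <- w$omega * t + w$phase
  val <- 0
  for (k in seq_along(w$harmonics))
    val <- val + w$harmonics[k] * sin(k * th)
  w$amplitude * val
}

# time-derivative of the waveform (per hour); used for tangency certificates
circadian_deriv <- function(t, w) {
  if (w$amplitude == 0) return(rep(0, length(t)))
  th <- w$omega * t + w$phase
  val <- 0
  for (k in seq_along(w$harmonics))
    val <- val + w$harmonics[k] * k * w$omega * cos(k * th)
  w$amplitude * val
}

#' @export
print.circadian_waveform <- function(x, ...) {
  cat(sprintf("Circadian waveform: amplitude %.4g, period %.4g h, phase %.4g rad, %d harmonic(s)\n",
              x$amplitude, 2 * pi / x$omega, x$phase, length(x$harmonics)))
  invisible(x)
}
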