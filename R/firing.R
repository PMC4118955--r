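#' Sigmoidal firing-rate function
#'
#' Mean population firing rate as a function of mean cell-body potential,
#' \deqn{Q(V) = Q_{max} / (1 + \exp(-(V - \theta)/\sigma)),}
#' the standard form used in the mutual-inhibition (Phillips-Robinson) model.
#' Strictly increasing, equal to \eqn{Q_{max}/2} at \eqn{V = \theta}, and
#' saturating to \eqn{Q_{max}} (resp. 0) for large positive (negative) V.
#'
#' @param V Potential in mV (vectorised).
#' @param p A \code{\link{pr_params}} object (only \code{Q_max}, \code{theta},
#'   \code{sigma} are used).
#' @return Firing rate in 1/s.
#' @export
firing_rate <- function(V, p) {
  p$Q_max / (1 + exp(-(V - p$theta) / p$sigma))
}

#' Derivative of the sigmoidal firing-rate function
#'
#' \eqn{Q'(V) = Q(V)(1 - Q(V)/Q_{max})/\sigma}; needed for the saddle-node
#' (fold) conditions of the slow manifold.
#'
#' @inheritParams firing_rate
#' @return dQ/dV in (1/s)/mV.
#' @export
firing_rate_deriv <- function(V, p) {
  q <- firing_rate(V, p)
  q * (1 - q / p$Q_max) / p$sigma
}

#' Hard-switch firing function
#'
#' Replaces the sigmoid by a step: the population fires at the mean rate
#' \code{Q_bar} when the potential exceeds the switch voltage \code{V_th} and
#' is silent otherwise. A potential exactly at \code{V_th} keeps the current
#' (silent) value: the switch requires a strict crossing, which avoids
#' chattering at tangencies.
#'
#' @param V Potential in mV (vectorised).
#' @param p A \code{\link{pr_switch_params}} object.
#' @return Firing rate in 1/s: \code{Q_bar} where \code{V > V_th}, else 0.
#' @export
firing_switch <- function(V, p) {
  ifelse(V > p$V_th, p$Q_bar, 0)
}
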