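# ---- slow manifold of the mutual-inhibition model ---------------------------
# With the neuronal potentials at quasi-equilibrium the fast subsystem reduces
# to the scalar equation
#   F(V_v) = V_v - D_v + nu_vm * Q(D_m - nu_mv * Q(V_v)) = 0,
# whose solutions (one or three) are the frozen-drive equilibria.  Folds
# (saddle-nodes) satisfy in addition dF/dV_v = 0, i.e.
#   g(V_v) = 1 - nu_vm * nu_mv * Q'(V_m) Q'(V_v) = 0.

# search window for V_v: outside theta +/- w the sigmoid slopes are too small
# for folds or extra equilibria
sm_window <- function(p, D_v = 0) {
  w <- p$sigma * log(4 * p$nu_vm * p$nu_mv * p$Q_max^2 / p$sigma^2 + 20)
  c(min(p$theta - w, D_v - p$nu_vm * p$Q_max - 1), max(p$theta + w, D_v + 1))
}

#' Frozen-drive equilibria on the slow manifold
#'
#' Solves the quasi-equilibrium equations of the fast (neuronal) subsystem for
#' fixed drives: \eqn{V_v = D_v - \nu_{vm} Q(V_m)},
#' \eqn{V_m = D_m - \nu_{mv} Q(V_v)}. Depending on the drives there are one
#' or three solutions; the transition between the two counts happens at
#' saddle-node bifurcations (see \code{\link{saddle_node_curve}}).
#'
#' @param p A \code{\link{pr_params}} object (sigmoid firing).
#' @param D_v VLPO drive (mV).
#' @param D_m MA drive (mV); defaults to \code{p$A}.
#' @return Data frame with one row per equilibrium: \code{V_v, V_m, Q_v, Q_m},
#'   \code{branch} (\code{"wake"} for the highest MA rate, \code{"sleep"} for
#'   the highest VLPO rate, \code{"saddle"} for the middle solution) and
#'   \code{residual} (largest absolute residual of the two equilibrium
#'   equations).
#' @export
slow_manifold_solve <- function(p, D_v, D_m = p$A) {
  stopifnot(inherits(p, "pr_params"))
  if (inherits(p, "pr_switch_params"))
    stop("slow_manifold_solve: use the sigmoid model; the hard switch has a ",
         "piecewise slow manifold", call. = FALSE)
  F <- function(Vv) Vv - D_v + p$nu_vm * firing_rate(D_m - p$nu_mv * firing_rate(Vv, p), p)
  win <- sm_window(p, D_v)
  vv <- seq(win[1L], win[2L], length.out = 2000L)
  fv <- F(vv)
  idx <- which(fv[-1L] * fv[-length(fv)] < 0)
  roots <- vapply(idx, function(i)
    uniroot(F, c(vv[i], vv[i + 1L]), tol = 1e-12)$root, numeric(1))
  roots <- sort(unique(roots))
  Vm <- D_m - p$nu_mv * firing_rate(roots, p)
  res <- pmax(abs(roots - D_v + p$nu_vm * firing_rate(Vm, p)),
              abs(Vm - D_m + p$nu_mv * firing_rate(roots, p)))
  n <- length(roots)
  branch <- if (n == 1L) {
    qm <- firing_rate(Vm, p); qv <- firing_rate(roots, p)
    if (qm >= qv) "wake" else "sleep"
  } else c("wake", "saddle", "sleep")[seq_len(n)]
  data.frame(V_v = roots, V_m = Vm,
             Q_v = firing_rate(roots, p), Q_m = firing_rate(Vm, p),
             branch = branch, residual = res, stringsAsFactors = FALSE)
}

# fold points for a fixed D_m: roots of g(V_v), with the corresponding drives.
# Returns a data frame with 0, 1 (cusp grazing) or 2+ rows sorted by D_v.
fold_points <- function(p, D_m) {
  g <- function(Vv) {
    Vm <- D_m - p$nu_mv * firing_rate(Vv, p)
    1 - p$nu_vm * p$nu_mv * firing_rate_deriv(Vm, p) * firing_rate_deriv(Vv, p)
  }
  win <- sm_window(p)
  vv <- seq(win[1L], win[2L], length.out = 4000L)
  gv <- g(vv)
  idx <- which(gv[-1L] * gv[-length(gv)] < 0)
  if (!length(idx)) return(data.frame(D_v = numeric(0), V_v = numeric(0),
                                      V_m = numeric(0), Q_v = numeric(0),
                                      Q_m = numeric(0)))
  roots <- vapply(idx, function(i)
    uniroot(g, c(vv[i], vv[i + 1L]), tol = 1e-13)$root, numeric(1))
  Vm <- D_m - p$nu_mv * firing_rate(roots, p)
  Dv <- roots + p$nu_vm * firing_rate(Vm, p)
  out <- data.frame(D_v = Dv, V_v = roots, V_m = Vm,
                    Q_v = firing_rate(roots, p), Q_m = firing_rate(Vm, p))
  out[order(out$D_v), , drop = FALSE]
}

#' Saddle-node (fold) curve of the slow manifold
#'
#' For each MA drive value on the grid, locates the two drives
#' \eqn{D_v^\pm} at which the number of frozen-drive equilibria changes
#' between one and three. The folds bound the bistable band in the
#' \eqn{(D_v, D_m)} plane: the wake state exists for \eqn{D_v < D_v^+}, the
#' sleep state for \eqn{D_v > D_v^-}. At each returned fold both the
#' equilibrium condition and the tangency (zero-derivative) condition hold.
#'
#' Grid values for which no fold exists (beyond the cusp, where the switch
#' between states becomes smooth) are reported with \code{NA} entries; the
#' hard-switch firing function has no smooth folds at all, and passing
#' \code{pr_switch_params} yields an all-\code{NA} curve with attribute
#' \code{no_folds}.
#'
#' @param p \code{\link{pr_params}} (or \code{\link{pr_switch_params}}).
#' @param D_m_grid Numeric vector of MA drive values (mV).
#' @return Object of class \code{saddle_node_curve}: data frame with columns
#'   \code{D_m, D_v_minus, D_v_plus, V_minus, V_plus, Q_m_minus, Q_m_plus}
#'   (fold drives, fold VLPO potentials and fold MA rates).
#' @export
saddle_node_curve <- function(p, D_m_grid) {
  stopifnot(inherits(p, "pr_params"), is.numeric(D_m_grid), all(is.finite(D_m_grid)))
  if (inherits(p, "pr_switch_params")) {
    out <- data.frame(D_m = D_m_grid, D_v_minus = NA_real_, D_v_plus = NA_real_,
                      V_minus = NA_real_, V_plus = NA_real_,
                      Q_m_minus = NA_real_, Q_m_plus = NA_real_)
    return(structure(out, class = c("saddle_node_curve", "data.frame"),
                     params = p, no_folds = TRUE))
  }
  rows <- lapply(D_m_grid, function(dm) {
    f <- fold_points(p, dm)
    if (nrow(f) < 2L)
      return(data.frame(D_m = dm, D_v_minus = NA_real_, D_v_plus = NA_real_,
                        V_minus = NA_real_, V_plus = NA_real_,
                        Q_m_minus = NA_real_, Q_m_plus = NA_real_))
    lo <- f[1L, ]; hi <- f[nrow(f), ]
    data.frame(D_m = dm, D_v_minus = lo$D_v, D_v_plus = hi$D_v,
               V_minus = lo$V_v, V_plus = hi$V_v,
               Q_m_minus = lo$Q_m, Q_m_plus = hi$Q_m)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("saddle_node_curve", "data.frame"),
            params = p, no_folds = all(is.na(out$D_v_plus)))
}

#' @export
print.saddle_node_curve <- function(x, ...) {
  if (isTRUE(attr(x, "no_folds"))) {
    cat("Saddle-node curve: no folds (discontinuous or monostable firing)\n")
  } else {
    ok <- !is.na(x$D_v_plus)
    cat(sprintf("Saddle-node curve over %d MA-drive values (%d with folds)\n",
                nrow(x), sum(ok)))
    cat(sprintf("  D_v- in [%.4g, %.4g] mV, D_v+ in [%.4g, %.4g] mV\n",
                min(x$D_v_minus[ok]), max(x$D_v_minus[ok]),
                min(x$D_v_plus[ok]), max(x$D_v_plus[ok])))
  }
  invisible(x)
}

# wake-branch solution (largest Q_m) for given drives; NA past the fold
wake_branch <- function(p, D_v, D_m = p$A) {
  sols <- slow_manifold_solve(p, D_v, D_m)
  w <- sols[sols$branch == "wake", , drop = FALSE]
  if (!nrow(w)) return(NULL)
  w[1L, ]
}

sleep_branch <- function(p, D_v, D_m = p$A) {
  sols <- slow_manifold_solve(p, D_v, D_m)
  s <- sols[sols$branch == "sleep", , drop = FALSE]
  if (!nrow(s)) return(NULL)
  s[1L, ]
}

# interpolators along the upper fold: D_v+ as a function of D_m and back.
# Built once per parameter set over [A, A + span]; the validity limit is the
# largest D_v+ attained before folds vanish (the "corner" beyond which wake
# cannot be maintained).
fold_plus_interp <- function(p, span = 10, step = 0.02) {
  key <- paste0("foldplus_", paste(signif(unlist(p[c("Q_max", "theta", "sigma",
        "nu_vm", "nu_mv", "A")]), 12), collapse = "_"), "_", span)
  hit <- .sleepdyn_cache[[key]]
  if (!is.null(hit)) return(hit)
  # fine resolution over the physiological effort range, coarse out to the
  # corner where the folds vanish and wake cannot be maintained at all
  dm <- c(seq(p$A, p$A + span, by = step),
          seq(p$A + span + 1, p$A + 60 * span, by = 2.5))
  cv <- saddle_node_curve(p, dm)
  ok <- !is.na(cv$D_v_plus)
  # keep the monotone-increasing part (up to the corner)
  dvp <- cv$D_v_plus[ok]; dmm <- cv$D_m[ok]; qmp <- cv$Q_m_plus[ok]
  if (length(dvp) < 2L)
    stop("fold_plus_interp: no fold curve for these parameters", call. = FALSE)
  last <- which(diff(dvp) <= 0)[1L]
  if (!is.na(last)) { dvp <- dvp[1:last]; dmm <- dmm[1:last]; qmp <- qmp[1:last] }
  res <- list(D_m_of_Dv = stats::approxfun(dvp, dmm),
              Dv_of_Dm = stats::approxfun(dmm, dvp),
              Qm_of_Dm = stats::approxfun(dmm, qmp),
              Dv_plus0 = dvp[1L], Dv_max = dvp[length(dvp)])
  .sleepdyn_cache[[key]] <- res
  res
}
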