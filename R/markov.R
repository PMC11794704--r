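#' One propagation step of the cell-cycle model
#'
#' Advances a phase-count state vector by one model timestep (1 hour):
#' \deqn{S_{n+1}[j] = \sum_i S_n[i] \, P[i,j] \, RM[i,j]}
#' i.e. each transition flux is weighted element-wise by the replication
#' matrix, so a completed mitosis (M -> G1) contributes two daughters while
#' every other flux conserves cell number. Equivalently
#' `S %*% (P * replication_matrix())`.
#'
#' @param S Numeric state vector of length 4 (counts per phase, ordered as
#'   [CC_PHASES]); counts may be fractional expected values.
#' @param P A `transition_matrix`.
#' @return The state vector one hour later.
#' @export
markov_step <- function(S, P) {
  S <- as.numeric(S)
  if (length(S) != 4L || any(!is.finite(S))) {
    stop("state vector must be 4 finite counts")
  }
  if (any(S < 0)) stop("state vector counts must be non-negative")
  P <- validate_transition_matrix(P)
  out <- as.numeric(S %*% (unclass(P) * replication_matrix()))
  names(out) <- CC_PHASES
  out
}

#' Deterministic trajectory of expected phase counts
#'
#' Iterates [markov_step()] from an initial state, producing expected counts
#' at hours `0, 1, ..., n_hours`. This is the forward model the fit compares
#' against observed counts: given only the initial timepoint and the
#' transition rates it reconstructs the whole series.
#'
#' @param S0 Initial state vector (counts per phase at hour 0).
#' @param P A `transition_matrix`.
#' @param n_hours Number of 1-hour steps (>= 0).
#' @return A [phase_counts] series with `n_hours + 1` rows.
#' @export
markov_trajectory <- function(S0, P, n_hours) {
  n_hours <- as.integer(n_hours)
  if (is.na(n_hours) || n_hours < 0) stop("n_hours must be >= 0")
  S0 <- as.numeric(S0)
  out <- matrix(NA_real_, nrow = n_hours + 1L, ncol = 4L)
  out[1L, ] <- S0
  if (n_hours > 0) {
    P <- validate_transition_matrix(P)
    W <- unclass(P) * replication_matrix()
    S <- S0
    if (length(S) != 4L || any(!is.finite(S)) || any(S < 0)) {
      stop("state vector must be 4 finite non-negative counts")
    }
    for (t in seq_len(n_hours)) {
      S <- as.numeric(S %*% W)
      out[t + 1L, ] <- S
    }
  }
  phase_counts(0:n_hours, out)
}

#' Root mean squared relative error between two phase-count series
#'
#' The fit's loss: for each phase, the root mean squared relative error over
#' timepoints,
#' \deqn{RMSRE = \sqrt{\tfrac1n \sum_t (c_{exp,t} - c_{obs,t})^2 / c_{obs,t}^2}}
#' then the arithmetic mean of the four per-phase values. Observed counts
#' appear in denominators and must be positive; a zero observed count is an
#' error unless a stabilizer `eps > 0` is supplied.
#'
#' @param pred,obs Phase-count series on identical time grids; `obs` supplies
#'   the denominators.
#' @param eps Optional non-negative stabilizer added to denominators
#'   (default 0: off).
#' @return Non-negative scalar loss.
#' @export
rmsre <- function(pred, obs, eps = 0) {
  pm <- counts_matrix(pred)
  om <- counts_matrix(obs)
  if (nrow(pm) != nrow(om) || any(abs(pred$time_h - obs$time_h) > 1e-9)) {
    stop("pred and obs must share the same time grid")
  }
  if (eps < 0) stop("eps must be non-negative")
  if (eps == 0 && any(om == 0)) {
    bad <- which(om == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("observed count is zero at t = %g h, phase %s; %s",
                 obs$time_h[bad[1L]], CC_PHASES[bad[2L]],
                 "supply eps > 0 to stabilize"))
  }
  rel2 <- (pm - om)^2 / (om + eps)^2
  mean(sqrt(colMeans(rel2)))
}

#' Loess noise floor for model-error values
#'
#' Smooths a set of error values (e.g. per-condition RMSRE) with a
#' second-order local regression, span 0.75 (tricube-weighted local
#' quadratic, computed exactly), and returns the fitted curve at the input
#' locations. Used to estimate the noise floor beneath which differences in
#' model error are not meaningful.
#'
#' @param x Numeric predictor values (at least 5).
#' @param y Numeric error values, same length as `x`.
#' @param span Loess span (fraction of points in each local window).
#' @return Numeric vector of fitted values at `x`.
#' @export
loess_noise_floor <- function(x, y, span = 0.75) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5L) stop("at least 5 points are required")
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}
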