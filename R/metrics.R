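#' Expected phase durations from homotypic transition rates
#'
#' The dwell time of a phase under the model is geometric with continuation
#' probability `P_ii`, so the expected duration is `1 / (1 - P_ii)` hours.
#' Total cycle duration is the sum over the three cycling phases (the
#' multinucleated state is absorbing and not part of the cycle).
#'
#' @param P A `transition_matrix` with homotypic rates < 1 for G1, S/G2, M.
#' @return A list of class `phase_durations` with `g1_hours`, `sg2_hours`,
#'   `m_hours` and `total_hours`.
#' @export
expected_durations <- function(P) {
  P <- validate_transition_matrix(P)
  p_ii <- diag(unclass(P))[CC_CYCLING]
  stuck <- CC_CYCLING[p_ii >= 1]
  if (length(stuck) > 0) {
    stop("homotypic rate is 1 for phase(s) ", paste(stuck, collapse = ", "),
         ": expected duration is infinite")
  }
  d <- 1 / (1 - p_ii)
  structure(list(g1_hours = unname(d["G1"]),
                 sg2_hours = unname(d["S/G2"]),
                 m_hours = unname(d["M"]),
                 total_hours = sum(d)),
            class = "phase_durations")
}

#' @export
print.phase_durations <- function(x, ...) {
  cat(sprintf("Inferred phase durations: G1 %.3g h, S/G2 %.3g h, M %.3g h (total %.3g h)\n",
              x$g1_hours, x$sg2_hours, x$m_hours, x$total_hours))
  invisible(x)
}

#' Build a durations object directly
#'
#' For durations obtained outside [expected_durations()] (e.g. reported
#' values); the total is always recomputed as the sum of the three phases.
#'
#' @param g1_hours,sg2_hours,m_hours Positive dwell times in hours.
#' @return A `phase_durations` object.
#' @export
phase_durations <- function(g1_hours, sg2_hours, m_hours) {
  stopifnot(g1_hours > 0, sg2_hours > 0, m_hours > 0)
  structure(list(g1_hours = g1_hours, sg2_hours = sg2_hours,
                 m_hours = m_hours,
                 total_hours = g1_hours + sg2_hours + m_hours),
            class = "phase_durations")
}

#' Mitotic success rate
#'
#' The fraction of M-exit flux that completes division into G1 rather than
#' failing into the multinucleated state:
#' \deqn{MSR = P_{M,G1} / (P_{M,G1} + P_{M,Multi})}
#'
#' @param P A `transition_matrix` with `P[M,G1] + P[M,Multi] > 0`.
#' @return A value in `[0, 1]`.
#' @export
mitotic_success_rate <- function(P) {
  P <- validate_transition_matrix(P)
  num <- P["M", "G1"]
  den <- P["M", "G1"] + P["M", "Multinucleated"]
  if (den <= 0) {
    stop("MSR is undefined: no M-exit flux (P[M,G1] + P[M,Multi] = 0)")
  }
  unname(num / den)
}

#' Highest-single-agent synergy ratios on phase durations
#'
#' For each cycling phase, the ratio of the combination treatment's inferred
#' duration to the larger of the two single-agent durations. A ratio of 1
#' means no benefit over the highest single agent, > 1 synergy (the
#' combination prolongs the phase more than either agent alone), < 1
#' antagonism.
#'
#' @param dur_combo,dur_agent_a,dur_agent_b `phase_durations` objects for the
#'   combination and the two single agents (order of the agents is
#'   immaterial).
#' @return A data frame with columns `phase`, `combo_hours`, `hsa_hours`,
#'   `ratio` and `call` (one of `"synergy"`, `"none"`, `"antagonism"`).
#' @export
hsa_ratio <- function(dur_combo, dur_agent_a, dur_agent_b) {
  pick <- function(d) c(d$g1_hours, d$sg2_hours, d$m_hours)
  combo <- pick(dur_combo)
  a <- pick(dur_agent_a)
  b <- pick(dur_agent_b)
  if (any(!is.finite(c(combo, a, b))) || any(c(combo, a, b) <= 0)) {
    stop("all durations must be finite and positive")
  }
  hsa <- pmax(a, b)
  ratio <- combo / hsa
  data.frame(phase = CC_CYCLING,
             combo_hours = combo,
             hsa_hours = hsa,
             ratio = ratio,
             call = ifelse(ratio > 1, "synergy",
                           ifelse(ratio < 1, "antagonism", "none")),
             stringsAsFactors = FALSE)
}

#' Agreement between predicted and observed counts
#'
#' A package-defined agreement score: `100 * (1 - mean(|pred - obs| / obs))`,
#' the mean taken over all phases and timepoints. 100 means perfect
#' agreement; a uniform 5\% relative error scores 95.
#'
#' @param pred,obs Phase-count series on identical time grids; `obs` must be
#'   positive everywhere.
#' @return Percentage agreement (can be negative for very poor predictions).
#' @export
prediction_agreement <- function(pred, obs) {
  pm <- counts_matrix(pred)
  om <- counts_matrix(obs)
  if (nrow(pm) != nrow(om) || any(abs(pred$time_h - obs$time_h) > 1e-9)) {
    stop("pred and obs must share the same time grid")
  }
  if (any(om == 0)) stop("observed counts must be positive")
  100 * (1 - mean(abs(pm - om) / om))
}
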