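# Independent oracles and fixture builders shared across the suite.

# Draw a ground-truth matrix from the biologically realistic regime the
# generator emulates: dwell times bracketing those inferred in TNBC cells.
rand_true_matrix <- function() {
  matrix_from_durations(g1_hours = runif(1, 6, 30),
                        sg2_hours = runif(1, 10, 60),
                        m_hours = runif(1, 3.5, 10),
                        msr = runif(1, 0.6, 1))
}

# Brute-force one propagation step as an explicit double loop over fluxes:
# destination j receives S[i] * P[i,j] * RM[i,j] from every source i.
brute_step <- function(S, P) {
  RM <- replication_matrix()
  out <- numeric(4)
  for (j in 1:4) {
    for (i in 1:4) out[j] <- out[j] + S[i] * P[i, j] * RM[i, j]
  }
  out
}

brute_trajectory <- function(S0, P, n_hours) {
  out <- matrix(NA_real_, n_hours + 1, 4)
  out[1, ] <- S0
  for (t in seq_len(n_hours)) out[t + 1, ] <- brute_step(out[t, ], P)
  out
}

# Direct evaluation of the loss formula: per-phase root mean squared
# relative error, then the arithmetic mean over phases.
brute_rmsre <- function(pm, om) {
  per_phase <- numeric(4)
  for (j in 1:4) {
    per_phase[j] <- sqrt(mean(((pm[, j] - om[, j]) / om[, j])^2))
  }
  mean(per_phase)
}

# Hand-rolled tricube-weighted local quadratic regression (the classical
# local-regression smoother), evaluated at each x.
brute_local_quadratic <- function(x, y, span = 0.75) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d)[q]
    w <- ifelse(d <= dmax, (1 - (d / dmax)^3)^3, 0)
    fit <- lm(y ~ x + I(x^2), weights = w)
    unname(predict(fit, newdata = data.frame(x = x0)))
  }, numeric(1))
}

# Continuity-corrected two-sample chi-square proportions test statistic.
brute_prop_chisq <- function(x1, n1, x2, n2) {
  p_pool <- (x1 + x2) / (n1 + n2)
  num <- abs(x1 / n1 - x2 / n2) - (1 / n1 + 1 / n2) / 2
  num <- max(num, 0)
  num^2 / (p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
}

# Plain counts matrix (timepoints x phases) of a series.
counts_mat <- function(series) {
  m <- as.matrix(as.data.frame(series)[, CC_PHASES])
  dimnames(m) <- NULL
  m
}

# A small feature table for one cell-frame given the two decision ratios.
feature_row <- function(nucleus_count, peri_nuc, nuc_cyto,
                        cyto_total = 1000, nuc_mean = 100) {
  data.frame(nucleus_count = nucleus_count,
             nuclear_total_intensity = nuc_cyto * cyto_total,
             cytoplasmic_total_intensity = cyto_total,
             nuclear_mean_intensity = nuc_mean,
             perinuclear_mean_intensity = peri_nuc * nuc_mean)
}

# Positive observed series for loss tests.
rand_obs_series <- function(n_hours = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phase_counts(0:n_hours,
               matrix(runif(4 * (n_hours + 1), 1, 100), ncol = 4))
}
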