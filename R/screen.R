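#' Percent inhibition relative to a matched control
#'
#' `100 * (1 - count / control_count)`: 0 for growth equal to control, 100
#' for complete inhibition. Cell counts are normalized to the same cell
#' line's vehicle + non-targeting control.
#'
#' @param count Treated cell count (non-negative).
#' @param control_count Matched control cell count (> 0).
#' @return Percentage inhibition (negative if the well outgrew its control).
#' @export
percent_inhibition <- function(count, control_count) {
  if (any(control_count <= 0)) stop("control_count must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  100 * (1 - count / control_count)
}

#' Two-sample proportions test for multinucleation fractions
#'
#' Compares the multinucleated fraction between two wells/conditions with the
#' standard two-sample proportions test (chi-square with Yates continuity
#' correction, via [stats::prop.test()]). Bonferroni correction across the
#' tested family is the caller's responsibility ([stats::p.adjust()] with
#' `method = "bonferroni"`).
#'
#' @param a_multi,a_total Multinucleated and total cell counts in group A.
#' @param b_multi,b_total Same for group B.
#' @return A list with `statistic` (chi-square), `p_value`, and `proportions`
#'   (the two sample fractions).
#' @export
multinucleation_test <- function(a_multi, a_total, b_multi, b_total) {
  counts <- c(a_multi, a_total, b_multi, b_total)
  if (any(counts < 0) || a_total <= 0 || b_total <= 0 ||
      a_multi > a_total || b_multi > b_total) {
    stop("invalid counts: need 0 <= multi <= total with total > 0")
  }
  ht <- stats::prop.test(x = c(a_multi, b_multi), n = c(a_total, b_total),
                         correct = TRUE)
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       proportions = unname(ht$estimate))
}

#' Z'-factor of a screening assay
#'
#' `1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Positive values
#' indicate sufficient dynamic range between positive and negative controls
#' for a valid screen.
#'
#' @param pos_values,neg_values Control readouts (at least 2 values each).
#' @return The Z'-factor (<= 1).
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L) {
    stop("need at least 2 values per control group")
  }
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n) stop("Z'-factor undefined: control means are equal")
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / abs(mu_p - mu_n)
}

#' Euclidean distance in z-scored phenotype space
#'
#' Z-scores each phenotype feature across the population of perturbations,
#' then returns the Euclidean distance between a perturbation's feature
#' vector and a reference (e.g. the non-targeting growth control) in z-space.
#' Features with zero variance across the population carry no information and
#' are dropped with a warning.
#'
#' @param v Numeric feature vector for the perturbation of interest.
#' @param reference Numeric feature vector of the reference perturbation.
#' @param population Numeric matrix (perturbations x features) used to
#'   estimate per-feature means and SDs; at least 2 rows.
#' @return Non-negative distance.
#' @export
feature_distance <- function(v, reference, population) {
  population <- as.matrix(population)
  if (nrow(population) < 2L) stop("population must have at least 2 rows")
  if (length(v) != ncol(population) || length(reference) != ncol(population)) {
    stop("v and reference must have one value per population feature")
  }
  mu <- colMeans(population)
  sdev <- apply(population, 2L, stats::sd)
  keep <- sdev > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped from the distance")
  }
  if (!any(keep)) return(0)
  zv <- (v[keep] - mu[keep]) / sdev[keep]
  zr <- (reference[keep] - mu[keep]) / sdev[keep]
  sqrt(sum((zv - zr)^2))
}

#' Gate a fixed cell into a cell-cycle state from DAPI and EdU intensities
#'
#' EdU positivity takes precedence: cells above the EdU cut are `EdU+`
#' (actively synthesizing DNA); remaining cells are split by total DAPI (DNA
#' content) into `2N/EdU-` below the 2N/4N boundary and `4N/EdU-` above it.
#' Thresholds are plate-specific and must be supplied.
#'
#' @param total_dapi,total_edu Per-cell total intensities (vectors recycle).
#' @param edu_cut EdU positivity threshold.
#' @param dapi_boundary DAPI boundary between 2N and 4N DNA content.
#' @return Character vector in `{"2N/EdU-", "EdU+", "4N/EdU-"}`.
#' @export
edu_gate <- function(total_dapi, total_edu, edu_cut, dapi_boundary) {
  if (missing(edu_cut) || missing(dapi_boundary) ||
      is.null(edu_cut) || is.null(dapi_boundary)) {
    stop("edu_cut and dapi_boundary thresholds must be supplied")
  }
  ifelse(total_edu > edu_cut, "EdU+",
         ifelse(total_dapi < dapi_boundary, "2N/EdU-", "4N/EdU-"))
}

#' Cleaved-PARP positivity threshold from vehicle controls
#'
#' The empirical 99th percentile of total nuclear cleaved-PARP intensity in
#' vehicle-treated control cells; cells above it are scored apoptotic.
#'
#' @param control_values Control intensities (non-empty; >= 100 values
#'   recommended for a stable tail quantile).
#' @param probs Quantile to use (default 0.99).
#' @return The intensity cutoff.
#' @export
cparp_threshold <- function(control_values, probs = 0.99) {
  if (length(control_values) == 0L) stop("control_values is empty")
  unname(stats::quantile(control_values, probs = probs, type = 7))
}

#' Normalized growth rate under treatment
#'
#' Growth-rate inhibition metric comparing treated to control doubling:
#' \deqn{2^{\log_2(c_t/c_0) / \log_2(ctrl_t/ctrl_0)} - 1}
#' 1 means growth identical to control, 0 cytostasis (no net change in
#' treated count), negative values net cell loss (bounded below by -1).
#'
#' @param count_t,count_0 Treated counts at end and start of treatment (> 0).
#' @param ctrl_t,ctrl_0 Control counts at the same times (> 0, and the
#'   control must have grown: `ctrl_t > ctrl_0`).
#' @return The normalized growth rate.
#' @export
growth_rate <- function(count_t, count_0, ctrl_t, ctrl_0) {
  if (any(c(count_t, count_0, ctrl_t, ctrl_0) <= 0)) {
    stop("all counts must be positive")
  }
  if (any(ctrl_t <= ctrl_0)) {
    stop("growth rate undefined: control did not grow (ctrl_t <= ctrl_0)")
  }
  2^(log2(count_t / count_0) / log2(ctrl_t / ctrl_0)) - 1
}
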