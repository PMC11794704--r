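#' Assign cell-cycle phases from reporter-localization features
#'
#' Classifies each cell-frame into G1, S/G2, M or Multinucleated from the
#' nuclear translocation pattern of the cell-cycle reporter. Two intensity
#' ratios drive the call: the perinuclear:nuclear mean-intensity ratio
#' (reporter exclusion from the nucleus) and the nuclear:cytoplasmic
#' total-intensity ratio (reporter concentration in the nucleus). Rules are
#' applied in order:
#' \enumerate{
#'   \item mononuclear, peri:nuclear mean > 0.8 and nuclear:cytoplasmic
#'     total < 0.5 -> S/G2 (reporter excluded from the nucleus);
#'   \item any nucleus count, nuclear:cytoplasmic total > 0.8 and
#'     peri:nuclear mean < 0.8 -> M (reporter concentrated in the nucleus);
#'   \item remaining mononuclear cells -> G1;
#'   \item remaining multinucleated cells -> Multinucleated.
#' }
#' Ties at exactly 0.8 / 0.5 fail the strict inequalities and fall through to
#' the remainder rules.
#'
#' @param features Data frame of cell features with columns `nucleus_count`,
#'   `nuclear_total_intensity`, `cytoplasmic_total_intensity`,
#'   `nuclear_mean_intensity`, `perinuclear_mean_intensity` (and optionally
#'   `cell_id`, used in error messages).
#' @param peri_nuclear_cut Threshold on the perinuclear:nuclear mean ratio.
#' @param nuc_cyto_cut_sg2 Upper threshold on the nuclear:cytoplasmic total
#'   ratio for the S/G2 rule.
#' @param nuc_cyto_cut_m Lower threshold on the nuclear:cytoplasmic total
#'   ratio for the M rule.
#' @return Character vector of phase labels, one per row of `features`.
#' @export
call_phase <- function(features, peri_nuclear_cut = 0.8,
                       nuc_cyto_cut_sg2 = 0.5, nuc_cyto_cut_m = 0.8) {
  req <- c("nucleus_count", "nuclear_total_intensity",
           "cytoplasmic_total_intensity", "nuclear_mean_intensity",
           "perinuclear_mean_intensity")
  miss <- setdiff(req, names(features))
  if (length(miss) > 0) {
    stop("features is missing column(s): ", paste(miss, collapse = ", "))
  }
  id <- if ("cell_id" %in% names(features)) features$cell_id
        else seq_len(nrow(features))
  bad <- features$cytoplasmic_total_intensity <= 0 |
    features$nuclear_mean_intensity <= 0
  if (any(bad)) {
    stop("zero intensity denominator for cell(s): ",
         paste(utils::head(id[bad], 5L), collapse = ", "))
  }
  if (any(features$nucleus_count < 1)) {
    stop("nucleus_count must be >= 1")
  }
  peri_nuc <- features$perinuclear_mean_intensity /
    features$nuclear_mean_intensity
  nuc_cyto <- features$nuclear_total_intensity /
    features$cytoplasmic_total_intensity
  mono <- features$nucleus_count == 1

  phase <- ifelse(mono, "G1", "Multinucleated")
  is_sg2 <- mono & peri_nuc > peri_nuclear_cut & nuc_cyto < nuc_cyto_cut_sg2
  is_m <- !is_sg2 & nuc_cyto > nuc_cyto_cut_m & peri_nuc < peri_nuclear_cut
  phase[is_m] <- "M"
  phase[is_sg2] <- "S/G2"
  phase
}

#' Tally phase labels into per-frame counts
#'
#' Counts labeled cells per frame and phase on a common time grid. Frames in
#' `times` with no cells are retained as all-zero rows.
#'
#' @param labels Data frame with columns `time_h` and `phase` (values in
#'   [CC_PHASES]).
#' @param times Optional numeric vector giving the full frame grid; defaults
#'   to the sorted unique times present in `labels`.
#' @return A data frame with `time_h` and one count column per phase.
#' @export
aggregate_phase_counts <- function(labels, times = NULL) {
  if (!all(c("time_h", "phase") %in% names(labels))) {
    stop("labels must have columns time_h and phase")
  }
  phase_index(unique(labels$phase))  # validates labels
  if (is.null(times)) times <- sort(unique(labels$time_h))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  ti <- match(labels$time_h, times)
  if (anyNA(ti)) stop("labels contain times not on the supplied grid")
  tab <- table(factor(ti, levels = seq_along(times)),
               factor(labels$phase, levels = CC_PHASES))
  out <- data.frame(time_h = times, check.names = FALSE)
  for (p in CC_PHASES) out[[p]] <- as.numeric(tab[, p])
  out
}

# Centered moving average with windows shrunk at the edges (partial windows
# averaged over the frames actually available).
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth per-frame counts and downsample to one value per hour
#'
#' Applies a centered moving average (default 5 frames, shrunk at the series
#' edges) to each phase's per-frame counts, then keeps one value per hour:
#' the smoothed value at the frame nearest each integer hour within the
#' observed span (ties broken toward the earlier frame).
#'
#' @param frame_counts Data frame with `time_h` (hours, strictly increasing
#'   frame times) and one count column per phase.
#' @param window Moving-average window in frames (odd, default 5).
#' @return A [phase_counts] series on an hourly grid.
#' @export
smooth_and_downsample <- function(frame_counts, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  cm <- counts_matrix(frame_counts)
  t <- frame_counts$time_h
  if (is.unsorted(t, strictly = TRUE)) stop("frame times must be strictly increasing")
  if (nrow(cm) < window) {
    stop("need at least ", window, " frames for a ", window, "-frame moving average")
  }
  sm <- apply(cm, 2L, moving_average, window = window)
  hours <- seq(ceiling(min(t) - 1e-9), floor(max(t) + 1e-9))
  idx <- vapply(hours, function(h) which.min(abs(t - h)), integer(1))
  phase_counts(hours, sm[idx, , drop = FALSE])
}

#' Normalize a phase-count series to its initial total
#'
#' Divides every count by the total cell number at the earliest timepoint, so
#' the first row sums to 1 across phases. Idempotent on already-normalized
#' series.
#'
#' @param series A phase-count series with positive total at the earliest
#'   timepoint.
#' @return A normalized [phase_counts] series; `normalization_basis` records
#'   the divisor.
#' @export
normalize_phase_counts <- function(series) {
  cm <- counts_matrix(series)
  basis <- sum(cm[1L, ])
  if (basis <= 0) stop("total count at the earliest timepoint must be positive")
  phase_counts(series$time_h, cm / basis, normalized = TRUE,
               normalization_basis = basis)
}
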