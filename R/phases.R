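#' Cell-cycle phase labels
#'
#' The four states of the cell-cycle model, in the canonical order used by
#' every matrix and count series in the package: the three cycling phases
#' followed by the permanent (absorbing) multinucleated state entered on
#' mitotic failure.
#'
#' @format Character vector of length 4.
#' @export
CC_PHASES <- c("G1", "S/G2", "M", "Multinucleated")

# Phases that cycle (have a finite expected dwell time).
CC_CYCLING <- c("G1", "S/G2", "M")

phase_index <- function(phase) {
  i <- match(phase, CC_PHASES)
  if (anyNA(i)) {
    stop("unknown phase label(s): ",
         paste(unique(phase[is.na(i)]), collapse = ", "))
  }
  i
}

#' Phase-count series container
#'
#' A `phase_counts` object is a data frame with a `time_h` column (hours,
#' strictly increasing) and one non-negative count column per phase in
#' [CC_PHASES]. Counts may be fractional: the population model propagates
#' expected counts. Attributes `normalized` (logical) and
#' `normalization_basis` (total count at the earliest timepoint used as the
#' divisor, `NA` if not normalized) record normalization state.
#'
#' @param time_h Numeric vector of timepoints in hours, strictly increasing.
#' @param counts Numeric matrix or data frame with one column per phase
#'   (ordered as [CC_PHASES]) and one row per timepoint.
#' @param normalized Logical flag; `TRUE` if counts were divided by the total
#'   at the earliest timepoint.
#' @param normalization_basis The divisor used, or `NA`.
#' @return A data frame of class `phase_counts`.
#' @export
phase_counts <- function(time_h, counts, normalized = FALSE,
                         normalization_basis = NA_real_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(time_h)) {
    stop("counts must have one row per timepoint")
  }
  if (ncol(counts) != length(CC_PHASES)) {
    stop("counts must have one column per phase (", length(CC_PHASES), ")")
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("time_h must be strictly increasing")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  out <- data.frame(time_h = as.numeric(time_h), check.names = FALSE)
  for (k in seq_along(CC_PHASES)) out[[CC_PHASES[k]]] <- as.numeric(counts[, k])
  structure(out,
            normalized = isTRUE(normalized),
            normalization_basis = as.numeric(normalization_basis),
            class = c("phase_counts", "data.frame"))
}

#' @export
print.phase_counts <- function(x, ...) {
  cat(sprintf("Phase-count series: %d timepoints, %.4g-%.4g h%s\n",
              nrow(x), min(x$time_h), max(x$time_h),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# Extract the counts of a phase_counts-like data frame as a plain matrix
# (timepoints x phases), validating the columns exist.
counts_matrix <- function(series) {
  miss <- setdiff(c("time_h", CC_PHASES), names(series))
  if (length(miss) > 0) {
    stop("series is missing column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(series[, CC_PHASES, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

as_phase_counts <- function(series) {
  if (inherits(series, "phase_counts")) return(series)
  phase_counts(series$time_h, counts_matrix(series))
}
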