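#' Read a per-cell feature table from CSV
#'
#' Expects the documented header: `cell_id`, `time_h`, `nucleus_count`,
#' `nuclear_total_intensity`, `cytoplasmic_total_intensity`,
#' `nuclear_mean_intensity`, `perinuclear_mean_intensity`. Rows failing
#' validation (non-finite or negative intensities, nucleus count < 1) are
#' reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of cell features.
#' @export
read_cell_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("cell_id", "time_h", "nucleus_count", "nuclear_total_intensity",
           "cytoplasmic_total_intensity", "nuclear_mean_intensity",
           "perinuclear_mean_intensity")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("feature CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  num <- req[-1]
  bad <- rep(FALSE, nrow(df))
  for (col in num) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- bad | !is.finite(x) | x < 0
    df[[col]] <- x
  }
  bad <- bad | df$nucleus_count < 1
  if (any(bad)) {
    # +1 for the header line
    stop("malformed feature row(s) at line(s): ",
         paste(utils::head(which(bad) + 1L, 10L), collapse = ", "))
  }
  df$nucleus_count <- as.integer(df$nucleus_count)
  df
}

#' Write a per-cell feature table to CSV
#'
#' @param features Data frame as returned by [simulate_agents()] or
#'   [read_cell_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_features <- function(features, path) {
  utils::write.csv(as.data.frame(features)[, c(
    "cell_id", "time_h", "nucleus_count", "nuclear_total_intensity",
    "cytoplasmic_total_intensity", "nuclear_mean_intensity",
    "perinuclear_mean_intensity")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phase-count series from CSV
#'
#' Expects columns `time_h`, `G1`, `S/G2`, `M`, `Multinucleated`. Time must
#' be strictly increasing; set `sort_time = TRUE` to sort shuffled rows
#' instead of rejecting them.
#'
#' @param path Path to a CSV file.
#' @param sort_time Sort rows by time instead of requiring sorted input.
#' @return A [phase_counts] series.
#' @export
read_phase_counts <- function(path, sort_time = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c("time_h", CC_PHASES), names(df))
  if (length(miss) > 0) {
    stop("phase-count CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (sort_time) df <- df[order(df$time_h), , drop = FALSE]
  if (is.unsorted(df$time_h, strictly = TRUE)) {
    stop("time_h must be strictly increasing (use sort_time = TRUE to sort)")
  }
  phase_counts(df$time_h, df[, CC_PHASES])
}

#' Write a phase-count series to CSV
#'
#' @param series A phase-count series.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_counts <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Stores the fitted matrices (free entries and pattern implied by phase
#' order), per-epoch error trace, seed and configuration, so a fit is fully
#' reproducible and auditable.
#'
#' @param fit A `markov_fit` from [fit_markov()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "markov_fit"))
  obj <- list(
    phases = CC_PHASES,
    best_matrix = unclass(fit$best_matrix),
    best_error = fit$best_error,
    top_matrices = lapply(fit$top_matrices, unclass),
    top_errors = fit$top_errors,
    error_trace = fit$error_trace,
    seed = fit$seed,
    normalization_basis = fit$normalization_basis,
    config = unclass(fit$config)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a fit result back from JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return A `markov_fit` object.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(fit_config, as.list(obj$config))
  tm <- obj$top_matrices
  top <- if (is.list(tm)) {
    lapply(tm, validate_transition_matrix)
  } else {
    lapply(seq_len(dim(tm)[1L]), function(i)
      validate_transition_matrix(tm[i, , ]))
  }
  structure(list(
    best_matrix = validate_transition_matrix(obj$best_matrix),
    best_error = obj$best_error,
    top_matrices = top,
    top_errors = obj$top_errors,
    error_trace = obj$error_trace,
    seed = obj$seed,
    normalization_basis = if (is.null(obj$normalization_basis)) NA_real_
                          else obj$normalization_basis,
    config = cfg
  ), class = "markov_fit")
}
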