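#' The constrained cell-cycle transition matrix
#'
#' The model's 4x4 row-stochastic transition matrix over the phases
#' `r paste(CC_PHASES, collapse = ", ")`. Its sparsity pattern is fixed:
#' cells may remain in their current phase, progress G1 -> S/G2 -> M,
#' complete mitosis (M -> G1, with division handled by the replication
#' matrix), or fail mitosis into the permanent multinucleated state
#' (M -> Multinucleated). The multinucleated row is fixed at identity
#' (absorbing). All other entries are structurally zero.
#'
#' @param mat A 4x4 numeric matrix obeying the pattern, or `NULL` to build
#'   one from the named rate arguments.
#' @param g1_g1,sg2_sg2,m_m Homotypic rates (probability of remaining in the
#'   phase over one 1-hour step), each in `[0, 1]`.
#' @param m_g1 Probability of completing mitosis into G1 in one step. The
#'   remaining M-row mass `1 - m_m - m_g1` is the mitotic-failure rate
#'   (M -> Multinucleated).
#' @return A matrix of class `transition_matrix` with phase dimnames.
#' @examples
#' P <- transition_matrix(g1_g1 = 0.87, sg2_sg2 = 0.97, m_m = 0.7,
#'                        m_g1 = 0.29)
#' @export
transition_matrix <- function(mat = NULL, g1_g1 = NULL, sg2_sg2 = NULL,
                              m_m = NULL, m_g1 = NULL) {
  if (is.null(mat)) {
    if (is.null(g1_g1) || is.null(sg2_sg2) || is.null(m_m) || is.null(m_g1)) {
      stop("supply either a full matrix or all of g1_g1, sg2_sg2, m_m, m_g1")
    }
    mat <- matrix(0, 4, 4, dimnames = list(CC_PHASES, CC_PHASES))
    mat["G1", "G1"] <- g1_g1
    mat["G1", "S/G2"] <- 1 - g1_g1
    mat["S/G2", "S/G2"] <- sg2_sg2
    mat["S/G2", "M"] <- 1 - sg2_sg2
    mat["M", "M"] <- m_m
    mat["M", "G1"] <- m_g1
    mat["M", "Multinucleated"] <- 1 - m_m - m_g1
    mat["Multinucleated", "Multinucleated"] <- 1
  }
  validate_transition_matrix(mat)
}

# Logical mask of the free (question-marked) entries.
free_entry_mask <- function() {
  free <- matrix(FALSE, 4, 4, dimnames = list(CC_PHASES, CC_PHASES))
  free["G1", c("G1", "S/G2")] <- TRUE
  free["S/G2", c("S/G2", "M")] <- TRUE
  free["M", c("G1", "M", "Multinucleated")] <- TRUE
  free["Multinucleated", "Multinucleated"] <- TRUE
  free
}

#' Validate a transition matrix against the model's constraints
#'
#' Checks dimension, the fixed sparsity pattern, entry bounds, row sums and
#' the absorbing multinucleated row, and returns the matrix with class
#' `transition_matrix` and phase dimnames attached.
#'
#' @param mat A 4x4 numeric matrix.
#' @param tol Numerical tolerance for row sums.
#' @return The validated `transition_matrix`.
#' @export
validate_transition_matrix <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || !identical(dim(mat), c(4L, 4L))) {
    stop("transition matrix must be a numeric 4x4 matrix")
  }
  dimnames(mat) <- list(CC_PHASES, CC_PHASES)
  free <- free_entry_mask()
  if (any(abs(mat[!free]) > tol)) {
    stop("transition matrix has mass on a forbidden (structurally zero) entry")
  }
  mat[!free] <- 0
  if (any(mat < -tol) || any(mat > 1 + tol)) {
    stop("transition rates must lie in [0, 1]")
  }
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > tol)) {
    bad <- CC_PHASES[abs(rs - 1) > tol]
    stop("row(s) do not sum to 1: ", paste(bad, collapse = ", "))
  }
  if (abs(mat["Multinucleated", "Multinucleated"] - 1) > tol) {
    stop("the Multinucleated state must be absorbing (P[Multi,Multi] = 1)")
  }
  mat <- pmin(pmax(mat, 0), 1)
  class(mat) <- c("transition_matrix", "matrix", "array")
  mat
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Cell-cycle transition matrix (1-hour step):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Identity transition matrix
#'
#' The matrix with every homotypic rate equal to 1 (every phase absorbing).
#' It satisfies the sparsity pattern and is the seed of the first training
#' epoch of [fit_markov()].
#'
#' @return A `transition_matrix`.
#' @export
identity_transition_matrix <- function() {
  validate_transition_matrix(diag(4))
}

#' The replication matrix
#'
#' Constant element-wise weights applied to transition fluxes during
#' propagation so that each completed mitosis (M -> G1 transition) yields two
#' daughter cells; every other permitted transition carries weight 1 and
#' forbidden transitions weight 0.
#'
#' @return A 4x4 numeric matrix with phase dimnames.
#' @export
replication_matrix <- function() {
  rm_ <- matrix(c(1, 1, 0, 0,
                  0, 1, 1, 0,
                  2, 0, 1, 1,
                  0, 0, 0, 1),
                nrow = 4, byrow = TRUE,
                dimnames = list(CC_PHASES, CC_PHASES))
  rm_
}

#' Draw a random transition matrix
#'
#' Free entries of each multi-entry row are drawn jointly uniform on the
#' probability simplex (flat Dirichlet); the multinucleated row is fixed at
#' identity. Uses R's global random number stream.
#'
#' @return A `transition_matrix`.
#' @export
random_transition_matrix <- function() {
  p <- random_free_params(1L)
  params_to_matrix(p)
}

# Draw n parameter vectors, rows uniform on their simplexes. Columns:
# g1_g1, g1_s, s_s, s_m, m_g1, m_m, m_multi. Returns an n x 7 matrix.
random_free_params <- function(n) {
  u <- stats::runif(n)
  v <- stats::runif(n)
  # flat Dirichlet on the 3-simplex via normalized exponentials
  e <- matrix(stats::rexp(3L * n), ncol = 3L)
  e <- e / rowSums(e)
  cbind(g1_g1 = u, g1_s = 1 - u,
        s_s = v, s_m = 1 - v,
        m_g1 = e[, 1L], m_m = e[, 2L], m_multi = e[, 3L])
}

params_to_matrix <- function(p) {
  p <- as.numeric(p)
  mat <- matrix(0, 4, 4, dimnames = list(CC_PHASES, CC_PHASES))
  mat["G1", "G1"] <- p[1L]; mat["G1", "S/G2"] <- p[2L]
  mat["S/G2", "S/G2"] <- p[3L]; mat["S/G2", "M"] <- p[4L]
  mat["M", "G1"] <- p[5L]; mat["M", "M"] <- p[6L]
  mat["M", "Multinucleated"] <- p[7L]
  mat["Multinucleated", "Multinucleated"] <- 1
  validate_transition_matrix(mat)
}

matrix_to_params <- function(mat) {
  c(g1_g1 = mat["G1", "G1"], g1_s = mat["G1", "S/G2"],
    s_s = mat["S/G2", "S/G2"], s_m = mat["S/G2", "M"],
    m_g1 = mat["M", "G1"], m_m = mat["M", "M"],
    m_multi = mat["M", "Multinucleated"])
}

#' Perturb a transition matrix toward a random matrix
#'
#' Returns the entrywise convex combination
#' `(1 - lr) * seed + lr * random_transition_matrix()`. Because each row of
#' both operands lies on the simplex, every perturbed row does too, so the
#' result is always a valid transition matrix. This is the candidate-update
#' rule of the random-search fit.
#'
#' @param seed_matrix A `transition_matrix` to perturb.
#' @param lr Learning rate in `(0, 1]`: the weight on the random matrix.
#' @return A `transition_matrix`.
#' @export
perturb_matrix <- function(seed_matrix, lr) {
  stopifnot(lr > 0, lr <= 1)
  seed_matrix <- validate_transition_matrix(seed_matrix)
  p <- (1 - lr) * matrix_to_params(seed_matrix) +
    lr * random_free_params(1L)[1L, ]
  params_to_matrix(p)
}

#' Build a transition matrix from target phase durations
#'
#' Inverts the expected-duration relation `duration = 1 / (1 - P_ii)` to set
#' homotypic rates, and splits the M-exit flux between successful division
#' (M -> G1) and mitotic failure (M -> Multinucleated) according to the
#' mitotic success rate. Convenient for constructing ground-truth matrices
#' for simulation from dwell times in hours.
#'
#' @param g1_hours,sg2_hours,m_hours Mean dwell times in hours, each >= 1
#'   (one step is the minimum dwell).
#' @param msr Mitotic success rate in `[0, 1]`: the fraction of M-exit flux
#'   that completes division rather than multinucleating.
#' @return A `transition_matrix`.
#' @examples
#' matrix_from_durations(7.9, 37.7, 3.4, msr = 0.97)
#' @export
matrix_from_durations <- function(g1_hours, sg2_hours, m_hours, msr = 1) {
  stopifnot(g1_hours >= 1, sg2_hours >= 1, m_hours >= 1,
            msr >= 0, msr <= 1)
  m_exit <- 1 / m_hours
  transition_matrix(g1_g1 = 1 - 1 / g1_hours,
                    sg2_sg2 = 1 - 1 / sg2_hours,
                    m_m = 1 - m_exit,
                    m_g1 = m_exit * msr)
}
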