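#' Configuration for the random-search fit
#'
#' Defaults reproduce the training schedule used throughout the package:
#' 15 epochs, 3000 random candidate matrices per epoch, the 5 lowest-error
#' matrices carried forward as seeds, and a learning rate of 0.1 for the
#' first epoch halving every 2 epochs.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param candidates_per_epoch Candidate matrices generated per epoch.
#' @param keep_top Number of lowest-error matrices kept as seeds for the
#'   next epoch; must not exceed `candidates_per_epoch`.
#' @param initial_lr Learning rate of the first epoch, in `(0, 1]`.
#' @param lr_halving_period Epochs between halvings of the learning rate.
#' @param seed Integer seed for the candidate-generation stream.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(epochs = 15L, candidates_per_epoch = 3000L,
                       keep_top = 5L, initial_lr = 0.1,
                       lr_halving_period = 2L, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs),
              candidates_per_epoch = as.integer(candidates_per_epoch),
              keep_top = as.integer(keep_top),
              initial_lr = as.numeric(initial_lr),
              lr_halving_period = as.integer(lr_halving_period),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(epochs >= 1, candidates_per_epoch >= 1, keep_top >= 1,
              keep_top <= candidates_per_epoch,
              initial_lr > 0, initial_lr <= 1, lr_halving_period >= 1)
  })
  class(cfg) <- "fit_config"
  cfg
}

# Score a batch of candidate parameter vectors (rows of `par`, columns as in
# random_free_params) against an observed count matrix. Propagates all
# candidates simultaneously with the same per-flux update as markov_step and
# returns the RMSRE of each candidate's trajectory (seeded at obs row 1,
# t = 0 included in the mean with zero error).
score_params_batch <- function(par, S0, om) {
  nT <- nrow(om)
  S0 <- unname(S0)
  om <- unname(om)
  g1 <- rep(S0[1L], nrow(par)); s <- rep(S0[2L], nrow(par))
  m <- rep(S0[3L], nrow(par)); mu <- rep(S0[4L], nrow(par))
  a <- par[, 1L]; b <- par[, 2L]; cc <- par[, 3L]; d <- par[, 4L]
  e <- par[, 5L]; f <- par[, 6L]; g <- par[, 7L]
  acc1 <- acc2 <- acc3 <- acc4 <- numeric(nrow(par))
  for (t in 2:nT) {
    g1n <- g1 * a + 2 * m * e
    sn <- g1 * b + s * cc
    mn <- s * d + m * f
    mun <- m * g + mu
    g1 <- g1n; s <- sn; m <- mn; mu <- mun
    acc1 <- acc1 + ((g1 - om[t, 1L]) / om[t, 1L])^2
    acc2 <- acc2 + ((s - om[t, 2L]) / om[t, 2L])^2
    acc3 <- acc3 + ((m - om[t, 3L]) / om[t, 3L])^2
    acc4 <- acc4 + ((mu - om[t, 4L]) / om[t, 4L])^2
  }
  (sqrt(acc1 / nT) + sqrt(acc2 / nT) + sqrt(acc3 / nT) + sqrt(acc4 / nT)) / 4
}

# Learning rate at a 1-indexed epoch under the halving schedule.
epoch_lr <- function(epoch, initial_lr, period) {
  initial_lr * 0.5^floor((epoch - 1) / period)
}

#' Fit the cell-cycle transition matrix to an observed count series
#'
#' Random-search optimization of the constrained transition matrix against an
#' hourly phase-count series, minimizing [rmsre()] between the observed
#' counts and the deterministic trajectory seeded at the first observed
#' timepoint. The first epoch is seeded with the identity matrix; each epoch
#' draws `candidates_per_epoch` candidates by perturbing the current seeds
#' toward fresh random matrices at the epoch's learning rate, and the
#' `keep_top` lowest-error matrices (candidates and prior seeds competing
#' together, i.e. elitism) seed the next epoch. Candidates are split equally
#' across seeds, any remainder going to the current best seed. Fitting
#' operates on normalized counts; raw counts are normalized internally by the
#' total at the earliest timepoint.
#'
#' @param obs A phase-count series (>= 2 timepoints, hourly grid, all counts
#'   positive). May be raw or already normalized.
#' @param config A [fit_config()].
#' @return An object of class `markov_fit`: `best_matrix`, `best_error`,
#'   `top_matrices` (list of matrices with `errors`), `error_trace` (best
#'   RMSRE per epoch, non-increasing), `config`, `seed`, and the
#'   `normalization_basis` applied.
#' @export
fit_markov <- function(obs, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  obs <- as_phase_counts(obs)
  om <- counts_matrix(obs)
  if (nrow(om) < 2L) stop("observed series needs at least 2 timepoints")
  if (all(om == 0)) stop("observed series is degenerate (all zeros)")
  if (any(om == 0)) {
    stop("observed counts must be positive everywhere (RMSRE denominators)")
  }
  basis <- NA_real_
  if (!isTRUE(attr(obs, "normalized"))) {
    basis <- sum(om[1L, ])
    om <- om / basis
  }
  S0 <- om[1L, ]

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  seeds <- matrix(matrix_to_params(identity_transition_matrix()), nrow = 1L)
  seed_err <- score_params_batch(seeds, S0, om)
  trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- epoch_lr(epoch, config$initial_lr, config$lr_halving_period)
    k <- nrow(seeds)
    n_per <- config$candidates_per_epoch %/% k
    extra <- config$candidates_per_epoch %% k
    # seeds are kept sorted by error; remainder candidates go to the best
    alloc <- rep(n_per, k)
    alloc[1L] <- alloc[1L] + extra
    cand <- matrix(NA_real_, nrow = config$candidates_per_epoch, ncol = 7L)
    row0 <- 0L
    for (i in seq_len(k)) {
      if (alloc[i] == 0L) next
      rnd <- random_free_params(alloc[i])
      cand[row0 + seq_len(alloc[i]), ] <-
        (1 - lr) * matrix(seeds[i, ], nrow = alloc[i], ncol = 7L,
                          byrow = TRUE) + lr * rnd
      row0 <- row0 + alloc[i]
    }
    cand_err <- score_params_batch(cand, S0, om)
    pool <- rbind(cand, seeds)
    pool_err <- c(cand_err, seed_err)
    keep <- order(pool_err)[seq_len(min(config$keep_top, nrow(pool)))]
    seeds <- pool[keep, , drop = FALSE]
    seed_err <- pool_err[keep]
    trace[epoch] <- seed_err[1L]
  }

  top <- lapply(seq_len(nrow(seeds)),
                function(i) params_to_matrix(seeds[i, ]))
  structure(list(best_matrix = top[[1L]],
                 best_error = seed_err[1L],
                 top_matrices = top,
                 top_errors = seed_err,
                 error_trace = trace,
                 config = config,
                 seed = config$seed,
                 normalization_basis = basis),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf("Cell-cycle Markov fit: %d epochs, final RMSRE %.4g\n",
              x$config$epochs, x$best_error))
  print(x$best_matrix)
  invisible(x)
}
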