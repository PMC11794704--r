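#' Configuration for the synthetic-data generators
#'
#' Describes a simulated live-cell experiment: a ground-truth transition
#' matrix, an initial phase composition, the acquisition grid (hours of
#' imaging, frames per hour; the default 4 corresponds to 15-minute frames
#' over a 72-hour experiment), and optional observation noise. The model's
#' timestep is 1 hour: agents change phase only at integer hours and hold
#' their phase across the frames within the hour.
#'
#' @param true_matrix Ground-truth `transition_matrix`.
#' @param initial_counts Non-negative counts per phase at time 0 (ordered as
#'   [CC_PHASES]), positive total. The default composition (600 G1, 350
#'   S/G2, 30 M, 20 Multinucleated) is a mostly-cycling population of about
#'   1000 cells with a small pre-existing multinucleated fraction, so every
#'   phase has positive counts throughout (required by the relative-error
#'   loss).
#' @param n_hours Experiment duration in hours (>= 2; default 72).
#' @param frames_per_hour Imaging frames per hour (default 4, i.e. every
#'   15 min).
#' @param intensity_noise_sd Gaussian noise SD added to the two emitted
#'   intensity ratios (default 0: noiseless features).
#' @param count_noise Observation-noise model for population counts: one of
#'   `"none"` (default), `"poisson"`, `"lognormal"`.
#' @param count_noise_sigma `sdlog` of the multiplicative lognormal noise
#'   (used only when `count_noise = "lognormal"`).
#' @param seed Integer seed; fans out to independent substreams for agent
#'   dynamics, feature emission and count noise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(true_matrix,
                       initial_counts = c(600, 350, 30, 20),
                       n_hours = 72L, frames_per_hour = 4L,
                       intensity_noise_sd = 0,
                       count_noise = c("none", "poisson", "lognormal"),
                       count_noise_sigma = 0.05,
                       seed = 1L) {
  true_matrix <- validate_transition_matrix(true_matrix)
  initial_counts <- as.numeric(initial_counts)
  if (length(initial_counts) != 4L || any(initial_counts < 0) ||
      sum(initial_counts) <= 0) {
    stop("initial_counts must be 4 non-negative values with positive total")
  }
  n_hours <- as.integer(n_hours)
  frames_per_hour <- as.integer(frames_per_hour)
  if (n_hours < 2L) stop("n_hours must be >= 2")
  if (frames_per_hour < 1L) stop("frames_per_hour must be >= 1")
  if (intensity_noise_sd < 0) stop("intensity_noise_sd must be >= 0")
  count_noise <- match.arg(count_noise)
  structure(list(true_matrix = true_matrix,
                 initial_counts = initial_counts,
                 n_hours = n_hours,
                 frames_per_hour = frames_per_hour,
                 intensity_noise_sd = intensity_noise_sd,
                 count_noise = count_noise,
                 count_noise_sigma = count_noise_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derive a deterministic substream seed from the master seed and a label.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 10007L + as.integer(h)) %% .Machine$integer.max
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate population-level phase counts
#'
#' Propagates the expected hourly phase counts with the replication-weighted
#' transition matrix (identical to [markov_trajectory()]) and optionally
#' applies observation noise per count: Poisson resampling or multiplicative
#' lognormal (mean-one). With `count_noise = "none"` the output equals the
#' deterministic trajectory exactly.
#'
#' @param config A [sim_config()].
#' @return A [phase_counts] series at hours `0..n_hours`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  traj <- markov_trajectory(config$initial_counts, config$true_matrix,
                            config$n_hours)
  if (config$count_noise == "none") return(traj)
  cm <- counts_matrix(traj)
  noisy <- with_seed(substream_seed(config$seed, "count_noise"), {
    if (config$count_noise == "poisson") {
      matrix(stats::rpois(length(cm), lambda = cm), nrow = nrow(cm))
    } else {
      s <- config$count_noise_sigma
      cm * matrix(stats::rlnorm(length(cm), meanlog = -s^2 / 2, sdlog = s),
                  nrow = nrow(cm))
    }
  })
  phase_counts(traj$time_h, noisy)
}

# Interior sampling boxes for the two emitted intensity ratios, per phase.
# Each box sits strictly inside the region the phase-calling rules assign to
# that phase, leaving a margin to the 0.8/0.5 decision boundaries.
ratio_boxes <- list(
  "G1" = list(peri = c(0.20, 0.75), nc = c(0.55, 0.78)),
  "S/G2" = list(peri = c(0.85, 1.40), nc = c(0.10, 0.45)),
  "M" = list(peri = c(0.10, 0.75), nc = c(0.85, 1.40)),
  "Multinucleated" = list(peri = c(0.10, 0.75), nc = c(0.55, 0.78))
)

# Emit reporter intensity features for a vector of phase labels. Ratios are
# drawn uniformly inside each phase's box, optionally jittered with Gaussian
# noise, then converted to raw intensities around typical magnitudes.
emit_features <- function(phase, noise_sd) {
  n <- length(phase)
  peri <- numeric(n)
  nc <- numeric(n)
  for (p in names(ratio_boxes)) {
    i <- phase == p
    if (!any(i)) next
    b <- ratio_boxes[[p]]
    peri[i] <- stats::runif(sum(i), b$peri[1L], b$peri[2L])
    nc[i] <- stats::runif(sum(i), b$nc[1L], b$nc[2L])
  }
  if (noise_sd > 0) {
    peri <- pmax(peri + stats::rnorm(n, sd = noise_sd), 0)
    nc <- pmax(nc + stats::rnorm(n, sd = noise_sd), 0)
  }
  cyto_total <- stats::runif(n, 800, 1200)
  nuc_mean <- stats::runif(n, 80, 120)
  data.frame(nucleus_count = ifelse(phase == "Multinucleated", 2L, 1L),
             nuclear_total_intensity = nc * cyto_total,
             cytoplasmic_total_intensity = cyto_total,
             nuclear_mean_intensity = nuc_mean,
             perinuclear_mean_intensity = peri * nuc_mean,
             check.names = FALSE)
}

#' Simulate an agent-based live-cell experiment
#'
#' Stochastic single-cell twin of the population model. Each agent holds its
#' phase for a geometric number of 1-hour steps (continuation probability =
#' homotypic rate); an agent leaving M either divides into two G1 daughters
#' (one keeps the parent id, one gets a fresh id) or becomes permanently
#' multinucleated, with odds `P[M,G1] : P[M,Multi]` (i.e. the mitotic success
#' rate). There is no cell death. Sampled at integer hours the agents follow
#' the discrete chain exactly; within the hour, each transition is placed at
#' a uniform random offset, so frame-level counts ramp smoothly between
#' hourly values as they do in a real time-lapse (a phase change is visible
#' from its sub-hour event time onward, and a daughter cell first appears at
#' its birth time). Each agent-frame is emitted with reporter intensity
#' features drawn inside its true phase's threshold region, so the phase
#' caller recovers the true phase exactly when `intensity_noise_sd = 0`.
#'
#' @param config A [sim_config()]; `initial_counts` are rounded to integers
#'   (total must remain positive).
#' @return A data frame of agent-frames with columns `cell_id`, `time_h`,
#'   `true_phase` and the five feature columns accepted by [call_phase()].
#'   Attribute `hourly_counts` holds the simulator's internal hourly tally as
#'   a [phase_counts] series.
#' @export
simulate_agents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- round(config$initial_counts)
  if (sum(n0) <= 0) stop("rounded initial counts must have positive total")
  P <- unclass(config$true_matrix)
  fph <- config$frames_per_hour
  offs <- (seq_len(fph) - 1L) / fph  # frame offsets within each hour

  state <- rep.int(seq_len(4L), n0)  # phase index per living cell
  ids <- seq_along(state)
  next_id <- length(state) + 1L
  tally <- matrix(NA_real_, nrow = config$n_hours + 1L, ncol = 4L)
  tally[1L, ] <- tabulate(state, nbins = 4L)
  frame_rows <- vector("list", config$n_hours + 1L)

  # cumulative transition probabilities per source phase
  cum <- t(apply(P, 1L, cumsum))

  with_seed(substream_seed(config$seed, "agents"), {
    for (h in seq_len(config$n_hours)) {
      u <- stats::runif(length(state))
      new_state <- integer(length(state))
      for (ph in 1:4) {
        i <- which(state == ph)
        if (length(i) == 0L) next
        # first column whose cumulative probability exceeds u
        new_state[i] <- 1L + findInterval(u[i], cum[ph, ], left.open = TRUE)
      }
      # sub-hour event time for cells that change phase during [h-1, h)
      tau <- rep.int(2, length(state))  # > 1: never reached within the hour
      changed <- which(state != new_state)
      tau[changed] <- stats::runif(length(changed))

      # frames of this hour interval: pre-transition phase before tau,
      # post-transition phase from tau onward
      n <- length(state)
      ph_frame <- matrix(state, nrow = n, ncol = fph)
      for (j in seq_len(fph)) {
        after <- offs[j] >= tau
        ph_frame[after, j] <- new_state[after]
      }
      fr <- list(cell_id = rep(ids, times = fph),
                 time_h = rep((h - 1L) + offs, each = n),
                 true_phase = as.integer(ph_frame))

      # divisions: cells that moved M -> G1 spawn a second G1 daughter,
      # visible from the same sub-hour event time as the parent's return
      divided <- which(state == 3L & new_state == 1L)
      if (length(divided) > 0L) {
        daughters <- seq.int(next_id, length.out = length(divided))
        next_id <- next_id + length(divided)
        d_tau <- tau[divided]
        d_keep <- lapply(seq_len(fph), function(j) {
          born <- offs[j] >= d_tau
          list(cell_id = daughters[born],
               time_h = rep.int((h - 1L) + offs[j], sum(born)),
               true_phase = rep.int(1L, sum(born)))
        })
        fr <- list(
          cell_id = c(fr$cell_id, unlist(lapply(d_keep, `[[`, "cell_id"))),
          time_h = c(fr$time_h, unlist(lapply(d_keep, `[[`, "time_h"))),
          true_phase = c(fr$true_phase,
                         unlist(lapply(d_keep, `[[`, "true_phase"))))
        ids <- c(ids, daughters)
        new_state <- c(new_state, rep.int(1L, length(divided)))
      }
      frame_rows[[h]] <- fr
      state <- new_state
      tally[h + 1L, ] <- tabulate(state, nbins = 4L)
    }
  })
  # final frame at t = n_hours
  frame_rows[[config$n_hours + 1L]] <-
    list(cell_id = ids, time_h = rep.int(config$n_hours, length(ids)),
         true_phase = state)

  agents <- data.frame(
    cell_id = unlist(lapply(frame_rows, `[[`, "cell_id")),
    time_h = unlist(lapply(frame_rows, `[[`, "time_h")),
    true_phase = CC_PHASES[unlist(lapply(frame_rows, `[[`, "true_phase"))],
    check.names = FALSE)
  agents <- agents[order(agents$time_h, agents$cell_id), , drop = FALSE]
  rownames(agents) <- NULL

  feats <- with_seed(substream_seed(config$seed, "features"),
                     emit_features(agents$true_phase,
                                   config$intensity_noise_sd))
  agents <- cbind(agents, feats)
  attr(agents, "hourly_counts") <- phase_counts(0:config$n_hours, tally)
  agents
}
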