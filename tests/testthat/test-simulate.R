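test_that("noiseless population simulation equals the model trajectory", {
  set.seed(3)
  P <- rand_true_matrix()
  cfg <- sim_config(P, n_hours = 24, seed = 4)
  sim <- simulate_population(cfg)
  tr <- markov_trajectory(cfg$initial_counts, P, 24)
  expect_identical(counts_mat(sim), counts_mat(tr))
})

test_that("all-homotypic rates freeze every phase count", {
  cfg <- sim_config(identity_transition_matrix(),
                    initial_counts = c(10, 20, 30, 40), n_hours = 12)
  sim <- simulate_population(cfg)
  expect_true(all(apply(counts_mat(sim), 2, function(col)
    all(col == col[1]))))
})

test_that("forced division doubles M into G1 and grows the total", {
  P <- transition_matrix(g1_g1 = 1, sg2_sg2 = 1, m_m = 0, m_g1 = 1)
  cfg <- sim_config(P, initial_counts = c(0, 0, 100, 0), n_hours = 2)
  sim <- simulate_population(cfg)
  expect_equal(unname(counts_mat(sim)[2, ]), c(200, 0, 0, 0))
  expect_equal(sum(counts_mat(sim)[2, ]), 200)
})

test_that("mixed-rate counts match hand propagation over 5 hours", {
  P <- transition_matrix(g1_g1 = 0.7, sg2_sg2 = 0.8, m_m = 0.4, m_g1 = 0.5)
  cfg <- sim_config(P, initial_counts = c(50, 30, 20, 0), n_hours = 5)
  sim <- simulate_population(cfg)
  expect_equal(counts_mat(sim), brute_trajectory(c(50, 30, 20, 0),
                                                 unclass(P), 5),
               tolerance = 1e-13)
})

test_that("count noise is reproducible and centered on the trajectory", {
  set.seed(10)
  P <- rand_true_matrix()
  cfg_p <- sim_config(P, initial_counts = c(6000, 3500, 300, 200),
                      n_hours = 24, count_noise = "poisson", seed = 8)
  s1 <- simulate_population(cfg_p)
  s2 <- simulate_population(cfg_p)
  expect_identical(counts_mat(s1), counts_mat(s2))
  tr <- counts_mat(markov_trajectory(cfg_p$initial_counts, P, 24))
  expect_lt(max(abs(counts_mat(s1) - tr) / tr), 0.2)

  cfg_l <- sim_config(P, initial_counts = c(6000, 3500, 300, 200),
                      n_hours = 24, count_noise = "lognormal",
                      count_noise_sigma = 0.05, seed = 8)
  sl <- simulate_population(cfg_l)
  expect_lt(max(abs(counts_mat(sl) - tr) / tr), 0.25)
})

test_that("agents never multinucleate when the failure rate is zero", {
  P <- matrix_from_durations(6, 15, 3, msr = 1)
  cfg <- sim_config(P, initial_counts = c(100, 50, 20, 0), n_hours = 24,
                    frames_per_hour = 1, seed = 5)
  agents <- simulate_agents(cfg)
  expect_false(any(agents$true_phase == "Multinucleated"))
})

test_that("a multinucleated agent never returns to a mononucleated phase", {
  P <- matrix_from_durations(6, 15, 3, msr = 0.5)
  cfg <- sim_config(P, initial_counts = c(100, 50, 40, 10), n_hours = 24,
                    frames_per_hour = 2, seed = 6)
  agents <- simulate_agents(cfg)
  by_cell <- split(agents$true_phase == "Multinucleated", agents$cell_id)
  expect_true(all(vapply(by_cell, function(z) all(diff(z) >= 0),
                         logical(1))))
})

test_that("frame times are strictly increasing within each agent", {
  P <- matrix_from_durations(6, 15, 3, msr = 0.8)
  cfg <- sim_config(P, initial_counts = c(50, 25, 10, 5), n_hours = 8,
                    frames_per_hour = 4, seed = 2)
  agents <- simulate_agents(cfg)
  by_cell <- split(agents$time_h, agents$cell_id)
  expect_true(all(vapply(by_cell,
                         function(z) !is.unsorted(z, strictly = TRUE),
                         logical(1))))
})

test_that("the agent population never shrinks (no death in the model)", {
  set.seed(20)
  P <- rand_true_matrix()
  cfg <- sim_config(P, initial_counts = c(200, 100, 30, 10), n_hours = 48,
                    frames_per_hour = 1, seed = 13)
  tally <- attr(simulate_agents(cfg), "hourly_counts")
  totals <- rowSums(counts_mat(tally))
  expect_true(all(diff(totals) >= 0))
  expect_true(all(diff(tally$Multinucleated) >= 0))
})

test_that("mean G1 dwell of many agents matches the geometric expectation", {
  # park post-G1 cells in a quasi-permanent S/G2 so the population is flat
  P <- transition_matrix(g1_g1 = 0.5, sg2_sg2 = 1 - 1e-9, m_m = 0.5,
                         m_g1 = 0.5)
  n <- 12000
  cfg <- sim_config(P, initial_counts = c(n, 0, 0, 0), n_hours = 40,
                    frames_per_hour = 1, seed = 17)
  agents <- simulate_agents(cfg)
  dwell <- tapply(agents$time_h[agents$true_phase != "G1"],
                  agents$cell_id[agents$true_phase != "G1"], min)
  expect_gt(length(dwell), 0.99 * n)  # censoring negligible at 40 h
  expect_equal(mean(dwell), 2, tolerance = 0.03)
})

test_that("noiseless emitted features are recalled perfectly; noise degrades", {
  P <- matrix_from_durations(8, 20, 4, 0.9)
  cfg <- sim_config(P, initial_counts = c(120, 60, 12, 8), n_hours = 12,
                    frames_per_hour = 2, seed = 21)
  agents <- simulate_agents(cfg)
  expect_equal(mean(call_phase(agents) == agents$true_phase), 1)

  cfg_n <- sim_config(P, initial_counts = c(120, 60, 12, 8), n_hours = 12,
                      frames_per_hour = 2, intensity_noise_sd = 0.3,
                      seed = 21)
  noisy <- simulate_agents(cfg_n)
  acc <- mean(call_phase(noisy) == noisy$true_phase)
  expect_lt(acc, 1)
  expect_gt(acc, 0.5)
})

test_that("agent phase fractions converge to the population model's", {
  P <- matrix_from_durations(7.9, 37.7, 3.4, 0.97)
  cfg <- sim_config(P, initial_counts = c(2400, 1400, 120, 80),
                    n_hours = 24, frames_per_hour = 1, seed = 30)
  tally <- counts_mat(attr(simulate_agents(cfg), "hourly_counts"))
  pop <- counts_mat(markov_trajectory(cfg$initial_counts, P, 24))
  fr_a <- tally / rowSums(tally)
  fr_p <- pop / rowSums(pop)
  expect_lt(max(abs(fr_a - fr_p)), 0.03)
})

test_that("simulation configs are validated", {
  P <- identity_transition_matrix()
  expect_error(sim_config(P, n_hours = 1), "n_hours")
  expect_error(sim_config(P, frames_per_hour = 0), "frames_per_hour")
  expect_error(sim_config(P, initial_counts = c(0, 0, 0, 0)), "positive")
  expect_error(sim_config(P, initial_counts = c(-1, 2, 3, 4)),
               "non-negative")
  expect_error(sim_config(P, intensity_noise_sd = -0.1), "noise")
  expect_error(sim_config(matrix(1, 4, 4)), "sum to 1|forbidden")
})
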