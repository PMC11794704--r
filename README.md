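# phasefit

Quantify cell-cycle dynamics from live-cell reporter imaging. `phasefit` is
aimed at groups running time-lapse experiments with translocation-based
cell-cycle sensors (e.g. in drug × knockdown studies of mitotic disruption):
it turns per-cell intensity features into phase calls, phase calls into
hourly population count series, and count series into interpretable
kinetics — phase durations, mitotic success rates, and drug-combination
synergy scores — via a constrained Markov model. Companion utilities score
fixed-cell screens (percent inhibition, multinucleation proportions tests,
Z′-factor, z-scored phenotype distances, EdU gating, normalized growth
rates).

## The model

Cells occupy one of four states — G1, S/G2, M, Multinucleated — and move
each hour according to a row-stochastic transition matrix `P` constrained to
the biology: stay in phase, advance G1→S/G2→M, complete mitosis (M→G1), or
fail mitosis into the permanent multinucleated state. Expected counts
propagate as

    S[n+1][j] = Σ_i S[n][i] · P[i,j] · RM[i,j]

where the replication matrix `RM` is 1 on every permitted transition except
`RM[M,G1] = 2`: each successful mitosis yields two daughters. The matrix is
fit to an observed hourly phase-count series by random search (15 epochs ×
3000 candidates, top-5 elitism, learning rate 0.1 halving every 2 epochs,
identity first seed) minimizing the mean over phases of the root mean
squared relative error (RMSRE). From the fitted matrix:

* phase duration `= 1/(1 − P[i,i])` hours (geometric dwell),
* mitotic success rate `MSR = P[M,G1] / (P[M,G1] + P[M,Multi])`,
* HSA synergy ratio per phase `= duration(combo) / max(duration(A), duration(B))`.

## A worked example

```r
library(phasefit)

# ground truth: a control-like condition (G1 7.9 h, S/G2 37.7 h, M 3.4 h)
truth <- matrix_from_durations(7.9, 37.7, 3.4, msr = 0.97)

# simulate a 72-h experiment at 15-min frames, ~10,000 starting cells
cfg <- sim_config(truth, initial_counts = c(6000, 3500, 300, 200),
                  n_hours = 72, frames_per_hour = 4, seed = 1)
agents <- simulate_agents(cfg)

# per-cell phase calls -> per-frame tallies -> smoothed hourly series
labels <- data.frame(time_h = agents$time_h, phase = call_phase(agents))
obs <- normalize_phase_counts(
  smooth_and_downsample(aggregate_phase_counts(labels), window = 5))

# fit the transition matrix and read the kinetics off it
fit <- fit_markov(obs, fit_config(seed = 1))
expected_durations(fit$best_matrix)
#> Inferred phase durations: G1 7.86 h, S/G2 37.5 h, M 3.45 h (total 48.8 h)
mitotic_success_rate(fit$best_matrix)
#> [1] 0.966978
```

The recovered durations agree with the generating truth to about 1% after a
full agent-level round trip (feature emission, phase calling, smoothing,
normalization, fitting). `hsa_ratio()` then compares fitted durations across
single-agent and combination conditions: a G1 ratio of 2 means the
combination doubles the G1 dwell relative to the stronger single agent.

## Layout

* `R/` — phase calling (`call_phase`), series processing
  (`aggregate_phase_counts`, `smooth_and_downsample`,
  `normalize_phase_counts`), the model (`markov_step`, `markov_trajectory`,
  `rmsre`, `fit_markov`), derived metrics (`expected_durations`,
  `mitotic_success_rate`, `hsa_ratio`, `prediction_agreement`), synthetic
  data (`sim_config`, `simulate_population`, `simulate_agents`), screen
  scoring, and CSV/JSON readers and writers.
* `vignettes/cell-cycle-markov.Rmd` — the methods vignette: model
  assumptions, numerical choices, generator design, and known limitations.
* `tests/testthat/` — oracle-backed unit tests, property tests, and
  end-to-end acceptance checks.
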