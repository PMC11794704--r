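Package: phasefit
Title: Cell-Cycle Phase Calling and Constrained Markov Models for
    Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying cell-cycle dynamics from live-cell
    reporter imaging features. Assigns cells to G1, S/G2, M or a permanent
    multinucleated state from nuclear, cytoplasmic and perinuclear intensity
    ratios; aggregates labels into smoothed hourly phase-count series; fits a
    constrained discrete-time Markov model with division (a replication
    matrix doubles the M-to-G1 flux) to the series by random-search
    optimization with a root-mean-squared-relative-error loss; and derives
    phase durations, mitotic success rates and highest-single-agent synergy
    ratios from the fitted transition rates. Includes agent-based and
    population-level synthetic-data generators, plus scoring utilities for
    fixed-cell screens (percent inhibition, multinucleation proportions
    tests, Z'-factor, z-scored phenotype distances, EdU gating, normalized
    growth rate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
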