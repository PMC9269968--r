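Package: caninesway
Title: Static Posturography and Center-of-Pressure Sway Analysis for Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying postural sway in quietly standing dogs from
    pressure-mat recordings. Computes the whole-body center-of-pressure (COP)
    trajectory from pressure frames, applies zero-phase low-pass filtering,
    selects analysis windows of acceptable standing from per-frame
    acceptability masks, and derives the standard set of sixteen time-domain
    sway measures (velocity, acceleration, range, RMS distance, 95% confidence
    ellipse area, sway area and frequency revolve, each in the craniocaudal,
    mediolateral and overall directions where applicable). Cohort-level
    analyses cover ICC(2,k) trial-to-trial reliability with F-based confidence
    intervals, fractional-lifespan age grouping, morphometric regressions,
    row-wise correlation matrices, forward stepwise group discrimination with
    ROC AUC, and joint-pain/proprioception interaction models. A seeded
    synthetic-cohort generator (AR(1) sway dynamics, Markov acceptability
    masks, Gaussian paw-pressure rendering) makes every stage testable without
    access to live animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
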