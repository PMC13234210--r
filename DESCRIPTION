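Package: leidar
Title: Leading Eigenvector Dynamics Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies recurrent whole-brain phase-locking states in
    resting-state BOLD time series using Leading Eigenvector Dynamics
    Analysis (LEiDA): band-pass filtering, Hilbert-transform instantaneous
    phase, per-timepoint phase-locking matrices and their leading
    eigenvectors, k-means clustering over a range of k with Dunn-index
    model selection, per-subject state occupancy, lifetime and
    switch-conditional transition metrics, mapping of state centroids onto
    canonical 7-network parcellations, and covariate-adjusted group
    inference (ANCOVA with FDR correction, BIC-approximated Bayes factors,
    partial Spearman correlations). Includes a synthetic-cohort generator
    that plants known phase-locking states and semi-Markov state dynamics
    so that every stage of the pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
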