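Package: epispread
Title: Individualized Seizure-Propagation Models via Epidemic Spreading on Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic SIR (susceptible-infected-recovered) spreading on
    weighted brain networks as a model of seizure propagation. Provides
    network construction and thresholding for functional-connectivity
    matrices, a Monte-Carlo SIR engine with an exact enumeration oracle,
    a total-correlation statistic for matching simulated propagation
    patterns to SEEG-style seizure patterns, per-patient and population
    parameter fitting over (beta, gamma, kappa) grids, seed-likelihood
    maps and greedy multi-ROI seed optimization, virtual-resection
    analysis with network covariates and stepwise regression, and a
    synthetic-cohort generator (exponential-distance-rule networks with
    known ground truth) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
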