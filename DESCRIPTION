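Package: fsdcm
Title: Spectral Dynamic Causal Modelling of a Two-Region Frontostriatal Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian effective-connectivity analysis for a two-region
    (left dorsolateral prefrontal cortex, left striatum) resting-state fMRI network.
    Fits a two-state (excitatory/inhibitory) neural mass model to BOLD cross-spectral
    densities per subject by variational Laplace, pools subjects with a parametric
    empirical Bayes (PEB) regression of connectivity on PANSS-8 symptom covariates,
    and compares symptom models by free-energy Bayesian model comparison. Includes a
    synthetic-cohort generator (clinical covariates, ground-truth connectivity,
    simulated BOLD series) so the whole pipeline is testable end to end, plus the
    published clinical and diagnostic tables as worked-example fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
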