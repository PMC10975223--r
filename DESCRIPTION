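Package: ponatdm
Title: Therapeutic Drug Monitoring and Dose Decision Support for Ponatinib in
    Chronic Myeloid Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trough-guided dosing of ponatinib in chronic myeloid
    leukemia: forward simulation of a two-compartment pharmacokinetic model
    with transit-compartment absorption, empirical-Bayes (MAP) prediction of
    the steady-state trough concentration from sparse random-time plasma
    samples under a log-normal population prior, exact contingency-table
    statistics (two-sided Fisher and Freeman-Halton tests implemented from
    first principles), classification of BCR-ABL1 molecular response on the
    International Scale and of trough concentrations against efficacy
    thresholds, a cardiovascular-risk-stratified dose-recommendation rule
    engine with auditable rationale traces, a synthetic cohort generator for
    end-to-end testing, and a cohort analysis pipeline producing structured
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
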