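Package: stratarx
Title: Prognostic-Stratum Matching and Policy Trees for Heterogeneous
    Treatment Effects
Version: 0.1.0
Authors@R:
    person("stratarx", "developers", email = "stratarx@example.org",
           role = c("aut", "cre"))
Description: Estimates heterogeneous treatment effects from confounded
    observational cohorts or imbalanced randomized-trial cohorts. Patients
    are stratified by model-predicted baseline outcome risk, arms are
    equalized within each stratum by exact optimal 1:1 matching, paired
    counterfactual outcome models with a cost-sensitive weight cancel the
    measurable part of residual unobserved confounding, and an
    interpretable axis-aligned policy tree assigns treatment to patient
    subgroups. Recommendations are validated on untreated external cohorts
    with sensitivity, specificity and negative predictive value. Ships a
    synthetic-cohort generator with known confounding structure and planted
    subgroup effects so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
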