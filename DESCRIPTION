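Package: dmnpredict
Title: Seed-Based Intrinsic Connectivity Biomarkers of Antidepressant Remission
Version: 0.1.0
Authors@R: person("dmnpredict", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting antidepressant treatment
    remission from pretreatment intrinsic functional connectivity of the
    default mode network. Covers motion and intensity-based volume
    censoring (framewise displacement and DVARS-like diagnostics),
    nuisance regression with the 24-parameter Volterra motion expansion,
    band-pass filtered task-residual time series, posterior cingulate
    seed connectivity maps with the Fisher z transform, permutation
    cluster-extent family-wise error inference for group prediction
    contrasts, and hierarchical logistic classification with ROC and
    leave-one-out cross-validation. Includes a seeded synthetic-cohort
    generator emulating the statistical structure of a two-session
    remitter/non-remitter/control imaging study, so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
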