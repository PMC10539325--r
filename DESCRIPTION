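Package: focondense
Title: Sequence-Based Analysis and Prediction of Fusion Oncoprotein Condensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sequence-derived physicochemical features of fusion
    oncoproteins (intrinsically disordered regions, low-complexity content,
    charge patterning statistics such as kappa, Omega and sequence charge
    decoration, acidic/basic tract metrics, prion-likeness and pi-contact
    propensity), selects discriminatory features by mutual-information
    filtering and Welch t-tests, clusters condensate-forming proteins into
    feature groups with multiscale-bootstrap confidence, trains a
    gradient-boosted classifier of cellular puncta formation with SHAP
    per-feature contributions, matches unseen sequences to feature groups,
    proposes condensation-weakening mutations, and summarises the
    fusion-parent condensate network. Includes a seeded generator of labeled
    synthetic chimeric sequences so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
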