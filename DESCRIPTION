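Package: cytofrisk
Title: Immunometabolic Risk Stratification from Mass-Cytometry Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for deriving per-patient immune features from gated
    mass-cytometry (CyTOF) events and plasma cytokines, embedding patients by
    metric multidimensional scaling on a squared-rank-difference distance,
    screening embedding coordinates and features against a binary
    hospital-acquired-infection outcome (bootstrap AUROC, Spearman
    correlation with Storey q-value control), and building an elastic-net
    logistic predicted score over selected features. Includes a
    transcriptomic validation stage that scores gene signatures per cell
    with expression-matched control genes and compares groups by
    Kruskal-Wallis with Dunn post-hoc adjustment, plus a seeded synthetic
    cohort generator with planted immunometabolic effects so every stage is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, Matrix, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), glmnet, pROC, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
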