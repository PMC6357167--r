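Package: pdsnet
Title: Pathway Dysregulation Scoring and Penalized Classification for
    Multi-Study Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A meta-analysis pipeline for building pathway-level classifiers
    of acquired drug resistance from heterogeneous gene-expression studies.
    Merges multiple studies with empirical-Bayes batch correction, converts
    gene-level expression to per-sample pathway dysregulation scores (PDS)
    via Hastie-Stuetzle principal curves, fits a binomial elastic-net model
    on the PDS matrix, tunes the (alpha, lambda) hyperparameters by
    Gaussian-process global optimization (EPSGO) under leave-one-study-out
    or leave-one-out cross-validation, and evaluates on held-out external
    samples projected into the training space. Includes a synthetic
    multi-study cohort generator with planted nonlinear pathway
    dysregulation for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lhs,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
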