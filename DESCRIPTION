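Package: fdapanel
Title: Fisher Discriminant Metabolite Panel Discovery with Longitudinal
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering small discriminating metabolite
    panels from two-cohort untargeted metabolomics tables and for tracking
    how a treated cohort's discriminant profile shifts toward the control
    cohort over an intervention.  Implements detection-limit filtering and
    square-root-of-two imputation, reference-cohort median normalization,
    orientation-free AUROC screening, Anderson-Darling-routed paired change
    tests with a leave-n-out false discovery proportion, two-class Fisher
    discriminant analysis with kernel-density-calibrated classification
    thresholds, exhaustive feature-subset search with greedy augmentation,
    leave-one-out cross-validation at several Type II error levels, and a
    longitudinal trajectory evaluation based on deviation scores referenced
    to the control cohort.  A synthetic-study generator with planted ground
    truth makes every stage testable without access to participant-level
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
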