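Package: motivAU
Title: Modeling Candidate Motivation from Facial Action Unit Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses facial action-unit (AU) and EMFACS-style emotion time
    series from video interviews into behavioral trace statistics (baseline,
    high-pass activity, trend, and supra-threshold episode rate, duration,
    area, and amplitude), and builds sparse linear motivation models from
    those features via correlation screening, iterative variance-inflation
    pruning, repeated cross-validated Lasso regularization, and stepwise
    simplification. Includes interrater reliability (Krippendorff's alpha),
    rater bias tests, Spearman validity analysis, matched-threshold ROC and
    confusion-probability curves for selection performance, and a synthetic
    cohort generator that emulates the statistical structure of webcam
    interview studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
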