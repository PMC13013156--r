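Package: stroopnorm
Title: Regression-Based Norming for a 50-Item Stroop Colour Word Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for regression-based norming of a four-task,
    50-item Stroop Colour Word Test. Provides stratified synthetic cohort
    generation, an exhaustive transformed-covariate linear model space with
    BIC-and-parsimony selection, demographic correction scores with
    band-midpoint norm grids, non-parametric outer and inner tolerance limits
    with the five-level Equivalent Score standardisation by rank subdivision,
    ROC-based clinical validation against dementia groups (Youden-optimal
    cut-points, AUC, predictive values), and supporting statistics (Cohen's
    f-squared power analysis via the noncentral F distribution,
    Greenhouse-Geisser epsilon, paired Cohen's d, Holm step-down adjustment).
    Ships the published correction formulas, correction grids and Equivalent
    Score cut-offs as a frozen, versioned norm set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
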