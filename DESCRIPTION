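Package: torrule
Title: Derivation and Validation of Termination-of-Resuscitation Rules
    for Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving and validating termination-of-resuscitation
    (TOR) clinical prediction rules from Utstein-style out-of-hospital
    cardiac arrest registries. Provides a seeded synthetic registry
    generator calibrated to published Japanese nationwide cohort
    characteristics, univariate and multivariable logistic regression via
    iteratively reweighted least squares with Wald odds-ratio confidence
    intervals, odds-ratio-threshold criteria selection into conjunction
    rules, and diagnostic evaluation (sensitivity, specificity, predictive
    values with Wilson score intervals, criteria-count ROC/AUC, and the
    futility misclassification rate), together with a full study-replay
    pipeline on synthetic or published aggregate data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
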