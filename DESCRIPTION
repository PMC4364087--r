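Package: cfqrmap
Title: Mapping Cystic Fibrosis Questionnaire-Revised Scores to EQ-5D-3L Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate EQ-5D-3L health utilities from the Cystic
    Fibrosis Questionnaire-Revised (CFQ-R). Implements EQ-5D-3L scoring with
    the UK TTO value set, CFQ-R domain scoring, three estimation approaches
    for ceiling-inflated utility data (ordinary least squares, upper-censored
    Tobit by maximum likelihood, and a two-part model combining a logit for
    full health with a truncated Gaussian regression), an eight-model
    specification ladder with predictor screening, misspecification and
    cross-validation diagnostics, an applicator for published domain-level
    mapping coefficients, and a calibrated synthetic cohort generator for
    testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), survival, numDeriv, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
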