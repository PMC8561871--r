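Package: matclass
Title: Maturity-Adjusted Weight-Status Classification for Adolescent Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-evaluating child weight status against biological
    rather than chronological age. Estimates biological age from the percent
    of predicted adult height attained (a Khamis-Roche-style prediction from
    current stature, weight and mid-parent height), classifies maturity timing
    with the conventional +/- 1 year rule, computes LMS-based BMI percentiles
    matched to either chronological or biological age, builds a composite
    cardiometabolic risk score from fasting glucose, HDL, LDL and mean
    arterial pressure z-scores, and compares the two classification schemes as
    predictors of later weight status and cardiometabolic risk via multinomial
    logistic models with deviance-dispersion scaling and AIC/BIC comparison.
    Includes a seeded synthetic-cohort generator with latent maturity truths
    so the full pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
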