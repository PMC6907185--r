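Package: lifelogpvar
Title: Panel Vector Autoregression for Lifelog-Based Early Warning of
    Depression Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting early warning signs of depression
    recurrence from smartphone and wearable lifelog panels. Provides K6
    and PHQ-9 questionnaire scoring, a seeded synthetic-cohort generator,
    weekly feature engineering (noon-to-noon sleep, long/short-sleep
    dummies, lunch-skip and UV standardisation, seasonal and
    pseudo-positive indicators), Little's MCAR test with a
    covariate-dependent-missingness variant and weighted regression
    imputation, a two-stage variable screen, and a panel vector
    autoregression with patient fixed effects estimated by GMM on
    forward-orthogonal-deviation data, with lag selection by the
    multivariate coefficient of determination, companion-matrix stability
    diagnostics, and back-transformation of coefficients to the K6 scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
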