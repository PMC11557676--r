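Package: taigrade
Title: Anatomical MRI Grading of Traumatic Axonal Injury and Ordinal Outcome Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading traumatic axonal injury (TAI) on early MRI and
    for modelling global outcome after traumatic brain injury. Implements a
    location ontology and four rule-based anatomical TAI grading systems
    (standard, Stockholm-style, GCS-based, Trondheim), construction of the
    6-month Glasgow Outcome Scale Extended endpoint (time-weighted
    interpolation and expectation-maximisation imputation), adjusted
    proportional-odds and binary logistic outcome models with log-volume
    covariate transforms, elastic-net penalised ordinal regression with
    cross-validated tuning and bootstrap stability selection, cross-validated
    AUC model comparison, the Jonckheere-Terpstra trend test, and a calibrated
    synthetic cohort generator for end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
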