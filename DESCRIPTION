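Package: digiphen
Title: Digital Phenotyping of Depression from Passive Smartphone Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw smartphone app-usage and gyroscope event streams into
    daily behavioral biomarkers (session times, open counts, sleep proxy,
    per-app-category use, angular-velocity activity), scores PHQ-9 depression
    questionnaires, trains class-balanced day-level depression classifiers
    (random forest, gradient boosting, RBF support vector machine), and emits
    a daily Mental Health Similarity Score (MHSS, 0-100) with
    majority-of-days verdicts. Includes cohort statistics (one-tailed Welch
    tests, Cohen's d, per-item correlations) and a calibrated synthetic
    event-stream generator so the whole pipeline is testable without any
    participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    xgboost,
    e1071,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
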