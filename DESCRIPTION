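Package: toysense
Title: Quantified Object-Play Analysis from Instrumented-Ball Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying canine object-play behaviour from an
    instrumented ball carrying a barometric pressure sensor and a 9-axis
    inertial measurement unit. Provides a synthetic-cohort generator with
    ground-truth bite logs, sensor-stream input/output with magnet-sync
    detection and trial segmentation, rule-based bite-event detection and
    per-trial feature engineering, correlation-based collinearity pruning,
    a binomial generalized linear model of placement outcome with adjusted
    odds ratios and estimated-marginal-mean likelihood curves, a Cohen
    f-squared power analysis for sample-size planning, and classification
    metrics (weighted precision/recall/F, Matthews correlation, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
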