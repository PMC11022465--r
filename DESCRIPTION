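Package: strollpipe
Title: IMU Gait Feature Extraction and Daily-Life Walking Ability Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline from raw inertial-measurement-unit (IMU)
    signals to estimates of walking ability in daily life. Provides a
    synthetic-signal and synthetic-cohort generator with exact ground truth;
    gait-event detection and a four-family gait-feature catalog
    (spatiotemporal, frequency, complexity, asymmetry) for instrumented
    two-minute walk tests; a zero-velocity-update (ZUPT) double-integration
    stage that turns multi-day single-sensor recordings into steps per day and
    average and maximum daily gait speed; correlation pruning,
    Kaiser-Meyer-Olkin adequacy and z-scoring for feature selection; principal
    component analysis with Kaiser retention, fixed-loading projection and a
    test-retest reliability panel (ICC(2,1), SEM, MDC, RMSE); and linear
    mixed models with forward selection of confounders and effect modifiers
    among the components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
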