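Package: playcog
Title: Gameplay Telemetry Featurization and Stacked-Ensemble Prediction of
    Preschool Cognitive Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for gamified cognitive assessment of
    preschool children from tablet gameplay telemetry. Simulates cohorts of
    children with known latent cognitive ability and ability-graded tap/drag
    event logs across a nine-game, forty-level battery; derives a taxonomy of
    per-level, per-game and across-game features (accuracy, latency, playtime,
    activity, interaction terms, a mas-o-menos composite, principal
    components); trains a repeated ten-fold cross-validated stack of feature
    selectors and learners whose top five models are combined through three
    stacking functions with fixed weights into a predicted cognitive ("DEEP")
    score; and evaluates agreement with the benchmark score via ICC(2,1),
    Pearson correlation with Fisher confidence intervals, Bland-Altman limits
    of agreement, error metrics, ROC analysis at a below-25th-percentile
    cutoff, and exposure/fine-motor bias checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
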