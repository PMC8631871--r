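Package: rosettecast
Title: Rosette Phenotyping Pipeline with Stage-Windowed Growth Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable analysis pipeline for
    top-view rosette phenotyping: tray-image simulation with fiducial corner
    markers, marker detection and projective rectification, per-cell cropping
    and scaling, segmentation evaluation metrics and trainable segmentation
    (dice + focal loss), shape-feature extraction (projected area, convex
    hull, perimeter, compactness), stage-windowed direct multi-horizon
    forecasting of projected area with gradient-boosted trees, allometric
    fresh-weight estimation chained onto the forecasts, and the statistical
    validation protocol (ANOVA, Tukey HSD, paired t-tests, Spearman
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    png,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
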