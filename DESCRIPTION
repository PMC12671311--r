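Package: hrvsleep
Title: Wearable Heart-Rate-Variability Pipelines for Modelling Self-Reported Sleep Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of wearable interbeat-interval, heart-rate,
    accelerometer and step-count streams together with morning diaries:
    artifact detection and interpolation for interbeat intervals, windowed
    Poincare descriptors (SD1, SD2, SDNN), automated sleep-period
    segmentation with transition trimming, resting-window filtering,
    wake-anchored daily feature aggregation, per-participant normalization,
    L1-penalized logistic models of high versus low sleep quality with
    sequential feature selection, balanced subject-held-out evaluation, and
    subgroup rank tests. Includes a synthetic cohort generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
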