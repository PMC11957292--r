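Package: motrack
Title: Label-Free Cell Tracking and Motility-Based Cell Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and region-of-interest tracking of single adherent
    cells in phase-contrast time-lapse image stacks, extraction of ten
    trajectory motility parameters (migration speed, turn frequencies and
    migration distances below angular thresholds, sum of turn angles,
    quiescent time, total migration length), correlation analysis, and
    linear/quadratic discriminant classification of two cell populations
    using Mahalanobis distances with stratified k-fold cross-validation.
    Includes a synthetic trajectory and phase-contrast scene generator with
    ground truth, so the full pipeline can be exercised and validated
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
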