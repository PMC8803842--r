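Package: prtkit
Title: Automated Scoring of the Pup Retrieval Test from Pose-Estimation Output
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Turns dam and pup pose-estimation tables into pup retrieval test
    (PRT) outcomes. Reads DeepLabCut-style coordinate exports, corrects
    tracking outliers with median-based movement and location criteria,
    standardizes pixel coordinates to millimeters against a cage landmark,
    evaluates nest and core-nest region-of-interest occupancy, extracts
    per-frame kinematic features, trains random-forest frame classifiers for
    maternal approach, carrying and digging (with majority-class
    undersampling, f1-optimal discrimination thresholds and minimum bout
    smoothing), scores retrieval success and retrieval time with a
    carry-before-nest-entry rule, and reproduces the validation statistics
    (confusion matrices, exact binomial confidence intervals, sensitivity and
    specificity under the class-0-positive convention, Pearson correlations).
    Includes a synthetic trial generator with frame-accurate ground truth so
    the full pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
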