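#' Fitted classifier presets
#'
#' Per-behavior settings fitted on the original PRT video dataset during
#' protocol development: random undersample ratio, f1-optimal
#' discrimination threshold and minimum bout length, together with the size
#' and class balance of the annotated training pools. These values are
#' dataset-specific presets, not universal constants: classifiers trained
#' on other recordings should refit the threshold with
#' [select_threshold()].
#'
#' @return Data frame with one row per behavior (approach, carry, digging).
#' @export
#' @examples
#' classifier_presets()
classifier_presets <- function() {
  data.frame(
    behavior = c("approach", "carry", "digging"),
    annotated_frames = c(10157L, 10157L, 18207L),
    present_pct = c(8.7, 13.9, 32.3),
    undersample_ratio = c(8.5, 16, 2),
    threshold = c(0.47, 0.47, 0.24),
    min_bout_ms = c(500, 200, 1000),
    stringsAsFactors = FALSE)
}

#' Benchmark confusion matrices
#'
#' The manual-versus-automated confusion matrices published with the
#' validation of the automated PRT protocol: frame-level matrices for the
#' approach, carry and digging classifiers on independent annotated videos,
#' and the trial-level retrieval-status matrix (60 trials). Cell layout
#' follows [confusion_counts()]: `a` manual 0 / predicted 0, `b` manual 1 /
#' predicted 0, `c` manual 0 / predicted 1, `d` manual 1 / predicted 1.
#'
#' Passing these to [classification_report()] with `positive_label = 0`
#' reproduces the published accuracy, sensitivity and specificity values.
#'
#' @return Named list of `confusion_counts` (approach, carry, digging,
#'   retrieval).
#' @export
#' @examples
#' classification_report(benchmark_matrices()$retrieval)
benchmark_matrices <- function() {
  list(
    approach = new_confusion(a = 24676L, b = 233L, c = 157L, d = 2618L),
    carry = new_confusion(a = 26155L, b = 120L, c = 76L, d = 1333L),
    digging = new_confusion(a = 14412L, b = 925L, c = 3218L, d = 9129L),
    retrieval = new_confusion(a = 16L, b = 2L, c = 6L, d = 36L))
}
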