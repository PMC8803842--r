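#' Undersample the majority (behavior-absent) class
#'
#' Behavior-present frames are rare, so training data are rebalanced by
#' keeping every present-class frame and randomly sampling
#' `floor(ratio * n_present)` absent-class frames without replacement.
#'
#' @param labels Integer 0/1 vector of frame annotations.
#' @param ratio Absent-to-present sampling ratio (> 0); e.g. the fitted
#'   presets use 8.5 for approach, 16 for carry and 2 for digging.
#' @param seed Integer seed making the sample reproducible.
#' @return Sorted integer vector of selected frame indices (1-based).
#' @export
undersample_majority <- function(labels, ratio, seed) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (ratio <= 0) stop("ratio must be positive")
  present <- which(labels == 1L)
  absent <- which(labels == 0L)
  if (length(present) == 0L || length(absent) == 0L)
    stop("both classes must be present to undersample")
  n_need <- floor(ratio * length(present))
  if (n_need > length(absent))
    stop(sprintf("undersampling needs %d absent frames but only %d exist",
                 n_need, length(absent)))
  set.seed(seed)
  sort(c(present, sample(absent, n_need, replace = FALSE)))
}

# f1 of the present class for binary predictions (internal).
f1_score <- function(predicted, labels) {
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Choose the f1-optimal discrimination threshold
#'
#' Scans a candidate set (the unique held-out probabilities united with a
#' 0.01-step grid) and returns the threshold maximizing the f1 of the
#' behavior-present class, with ties broken toward the lowest threshold
#' (favoring sensitivity). A frame is predicted present when its
#' probability is greater than or equal to the threshold.
#'
#' @param probabilities Held-out present-class probabilities in \[0, 1\].
#' @param labels Matching 0/1 annotations with at least one positive.
#' @return The selected threshold (a single number in (0, 1\]).
#' @export
select_threshold <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (length(probabilities) != length(labels)) stop("length mismatch")
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (sum(labels == 1L) == 0L)
    stop("no positive labels: threshold undefined")
  cand <- sort(unique(c(seq(0.01, 0.99, by = 0.01), probabilities)))
  cand <- cand[cand > 0 & cand <= 1]
  f1s <- vapply(cand, function(t)
    f1_score(as.integer(probabilities >= t), labels), 0)
  best <- max(f1s)
  cand[which(f1s >= best - 1e-12)[1L]]
}

#' Train a random-forest frame classifier
#'
#' Trains a probability forest for one behavior with the protocol's
#' hyperparameters: 2000 trees, sqrt feature subsampling, minimum node size
#' 1. Annotated frames are split 75:25 into train and test (stratified by
#' class, seeded); the majority class of the *training* split is
#' undersampled at `undersample_ratio`; the discrimination threshold is
#' fitted on the untouched held-out 25% with [select_threshold()] unless a
#' preset threshold is supplied.
#'
#' @param features Feature data frame from [extract_features()] (rows
#'   aligned with `labels`).
#' @param labels Integer 0/1 frame annotations.
#' @param behavior Behavior name stored in the bundle.
#' @param undersample_ratio Absent:present ratio for
#'   [undersample_majority()]; `NULL` disables undersampling.
#' @param seed Integer seed (mandatory; recorded in the bundle) controlling
#'   the split, the undersampling and the forest.
#' @param num_trees Number of trees (default 2000).
#' @param split Training fraction (default 0.75).
#' @param min_bout_ms Minimum bout length (ms) stored for
#'   [enforce_min_bout()] at prediction time.
#' @param threshold Optional fixed discrimination threshold; `NULL` fits it
#'   on the held-out split.
#' @return List with `bundle` (class `classifier_bundle`) and `holdout`
#'   (indices, probabilities, labels and f1 on the 25% split).
#' @export
train_forest <- function(features, labels, behavior = "behavior",
                         undersample_ratio = NULL, seed,
                         num_trees = 2000L, split = 0.75,
                         min_bout_ms = 0, threshold = NULL) {
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features and labels are not aligned")
  if (length(unique(labels)) < 2L)
    stop("training data contain a single class")

  set.seed(seed)
  train_idx <- sort(unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(labels == cl)
    sample(idx, floor(split * length(idx)))
  })))
  test_idx <- setdiff(seq_along(labels), train_idx)
  if (length(unique(labels[train_idx])) < 2L)
    stop("training split contains a single class")

  if (!is.null(undersample_ratio)) {
    keep <- undersample_majority(labels[train_idx], undersample_ratio,
                                 seed = seed + 1L)
    train_idx <- train_idx[keep]
  }

  fit <- ranger::ranger(
    x = features[train_idx, , drop = FALSE],
    y = factor(labels[train_idx], levels = c(0L, 1L)),
    num.trees = num_trees,
    mtry = floor(sqrt(ncol(features))),
    min.node.size = 1L,
    splitrule = "gini",
    probability = TRUE,
    seed = seed,
    num.threads = 1L)

  holdout_prob <- ranger_prob(fit, features[test_idx, , drop = FALSE])
  if (is.null(threshold))
    threshold <- select_threshold(holdout_prob, labels[test_idx])

  bundle <- structure(
    list(behavior = behavior, model = fit, threshold = threshold,
         min_bout_ms = min_bout_ms, undersample_ratio = undersample_ratio,
         num_trees = num_trees, seed = seed,
         feature_names = colnames(features)),
    class = "classifier_bundle")
  holdout <- list(index = test_idx, probabilities = holdout_prob,
                  labels = labels[test_idx],
                  f1 = f1_score(as.integer(holdout_prob >= threshold),
                                labels[test_idx]))
  list(bundle = bundle, holdout = holdout)
}

# Present-class probability from a ranger probability forest (internal).
ranger_prob <- function(fit, features) {
  p <- stats::predict(fit, data = features, num.threads = 1L)$predictions
  p[, "1"]
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf(
    "classifier_bundle '%s': %d trees, threshold %.3f, min bout %g ms\n",
    x$behavior, x$num_trees, x$threshold, x$min_bout_ms))
  invisible(x)
}

#' Predict frame labels with a classifier bundle
#'
#' A frame is labelled present (1) when its forest probability is greater
#' than or equal to the bundle's discrimination threshold. The feature
#' columns must match the registry the bundle was trained on.
#'
#' @param bundle A `classifier_bundle` from [train_forest()].
#' @param features Feature data frame for the frames to classify.
#' @return Integer 0/1 vector, one element per row of `features`.
#' @export
predict_frames <- function(bundle, features) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  if (!identical(colnames(features), bundle$feature_names))
    stop("feature registry mismatch: features do not match the columns ",
         "the bundle was trained on")
  as.integer(ranger_prob(bundle$model, features) >= bundle$threshold)
}

#' Remove bouts shorter than a minimum duration
#'
#' Every maximal run of 1s shorter than `round(min_bout_ms / 1000 * fps)`
#' frames (minimum 1) is set to 0; longer runs are untouched. The operation
#' never creates 1s and is idempotent. Fitted presets use 500 ms for
#' approach, 200 ms for carry and 1000 ms for digging.
#'
#' @param labels Integer 0/1 vector of frame labels.
#' @param min_bout_ms Minimum bout duration in milliseconds.
#' @param fps Frames per second.
#' @return Smoothed 0/1 vector.
#' @export
enforce_min_bout <- function(labels, min_bout_ms, fps) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  min_frames <- max(1L, as.integer(round(min_bout_ms / 1000 * fps)))
  r <- rle(labels)
  r$values[r$values == 1L & r$lengths < min_frames] <- 0L
  inverse.rle(r)
}

#' Run-length bout representation of frame labels
#'
#' @param labels Integer 0/1 vector.
#' @param fps Optional frames per second; adds a `duration_ms` column.
#' @return Data frame with 0-based inclusive `start_frame` / `end_frame`,
#'   one row per maximal run of 1s (empty for all-absent labels).
#' @export
labels_to_bouts <- function(labels, fps = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  out <- data.frame(start_frame = starts[keep] - 1L,
                    end_frame = ends[keep] - 1L)
  if (!is.null(fps))
    out$duration_ms <- (out$end_frame - out$start_frame + 1L) / fps * 1000
  out
}

#' Rebuild frame labels from bouts
#'
#' Inverse of [labels_to_bouts()].
#'
#' @param bouts Data frame with 0-based `start_frame` / `end_frame`.
#' @param n_frames Total frame count.
#' @return Integer 0/1 vector of length `n_frames`.
#' @export
bouts_to_labels <- function(bouts, n_frames) {
  labels <- integer(n_frames)
  for (i in seq_len(nrow(bouts)))
    labels[(bouts$start_frame[i] + 1L):(bouts$end_frame[i] + 1L)] <- 1L
  labels
}

#' Save / load a classifier bundle
#'
#' A bundle directory holds the serialized forest (`model.rds`) and a JSON
#' manifest with behavior, threshold, minimum bout length, undersample
#' ratio, seed and the feature-name registry.
#'
#' @param bundle A `classifier_bundle`.
#' @param dir Directory to create/read.
#' @return `dir` (save) or the bundle (load).
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- bundle[c("behavior", "threshold", "min_bout_ms",
                       "undersample_ratio", "num_trees", "seed",
                       "feature_names")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  saveRDS(bundle$model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(c(manifest["behavior"],
              list(model = readRDS(file.path(dir, "model.rds"))),
              manifest[c("threshold", "min_bout_ms", "undersample_ratio",
                         "num_trees", "seed", "feature_names")]),
            class = "classifier_bundle")
}
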