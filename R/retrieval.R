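#' Score retrieval success and retrieval time
#'
#' A trial is scored as a successful retrieval when at least one pup body
#' part enters the nest ROI and carry behavior was observed in the three
#' seconds before entering. "Entering" is the false-to-true transition of
#' the pup's nest occupancy; a trial that starts with the pup already in
#' the nest counts as an entry at frame 0 with an empty look-back window,
#' which cannot qualify. The look-back window is left-closed, right-open
#' (`[entry - round(carry_window_s * fps), entry)`), clipped at frame 0.
#' Every entry event is examined in order; the first qualifying one sets
#' `retrieval_time_s = entry_frame / fps`. If no entry qualifies (e.g. the
#' pup appears inside the ROI because the nest shifted, with no carry), the
#' trial is not retrieved and is assigned the maximum trial time.
#'
#' Carry labels fed here should already be minimum-bout smoothed.
#'
#' @param pup_nest_occupancy Logical (or 0/1) per-frame vector from
#'   [roi_occupancy()] with `animal = "pup"`, `region = "nest"`,
#'   `mode = "any"`.
#' @param carry_labels Integer 0/1 per-frame carry labels, same length.
#' @param fps Frames per second.
#' @param carry_window_s Look-back window in seconds (default 3).
#' @param max_trial_s Maximum trial time in seconds (default 90).
#' @return List with `retrieved` (0/1 integer) and `retrieval_time_s`.
#' @export
#' @examples
#' occ <- rep(c(FALSE, TRUE), c(300, 600))
#' carry <- integer(900); carry[273:300] <- 1L
#' score_retrieval(occ, carry, fps = 10)  # retrieved at 30.0 s
score_retrieval <- function(pup_nest_occupancy, carry_labels, fps,
                            carry_window_s = 3, max_trial_s = 90) {
  occ <- as.logical(pup_nest_occupancy)
  carry <- as.integer(carry_labels)
  if (length(occ) != length(carry))
    stop(sprintf("occupancy length %d does not match carry length %d",
                 length(occ), length(carry)))
  if (fps <= 0) stop("fps must be positive")
  n <- length(occ)
  w <- as.integer(round(carry_window_s * fps))
  entries <- which(occ & !c(FALSE, occ[-n]))  # 1-based entry frames
  for (e in entries) {
    lo <- max(1L, e - w)
    if (lo <= e - 1L && any(carry[lo:(e - 1L)] == 1L))
      return(list(retrieved = 1L, retrieval_time_s = (e - 1L) / fps))
  }
  list(retrieved = 0L, retrieval_time_s = max_trial_s)
}

#' Latency, total duration and bout count of a behavior
#'
#' @param labels Integer 0/1 per-frame labels (minimum-bout smoothed).
#' @param fps Frames per second.
#' @param max_trial_s Assigned as latency when the behavior never occurs.
#' @return List with `latency_s` (time of the first present frame),
#'   `total_duration_s` and `bout_count`.
#' @export
behavior_summary <- function(labels, fps, max_trial_s = 90) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  first <- which(labels == 1L)[1]
  list(
    latency_s = if (is.na(first)) max_trial_s else (first - 1L) / fps,
    total_duration_s = sum(labels) / fps,
    bout_count = nrow(labels_to_bouts(labels)))
}

#' Score a full trial from a calibrated track
#'
#' Convenience wrapper running feature extraction, per-behavior prediction
#' and minimum-bout smoothing, pup nest occupancy, retrieval scoring and
#' per-behavior summaries for one trial.
#'
#' @param track_mm A corrected [pose_track()] in mm.
#' @param roi_mm The matching [roi_config()] in mm.
#' @param bundles Named list of `classifier_bundle`s; must contain
#'   `"carry"`, typically also `"approach"` and `"digging"`.
#' @param carry_window_s,max_trial_s See [score_retrieval()].
#' @param windows_s Rolling windows for [extract_features()].
#' @return Object of class `retrieval_result`: `retrieved`,
#'   `retrieval_time_s`, and per behavior `latency_s`, `total_duration_s`,
#'   `bout_count`, plus the smoothed label vectors.
#' @export
score_trial <- function(track_mm, roi_mm, bundles, carry_window_s = 3,
                        max_trial_s = 90, windows_s = c(0.2, 0.5, 1.0)) {
  if (!("carry" %in% names(bundles)))
    stop("bundles must include a 'carry' classifier")
  features <- extract_features(track_mm, roi_mm, windows_s = windows_s)
  fps <- track_mm$fps
  labels <- lapply(bundles, function(b)
    enforce_min_bout(predict_frames(b, features), b$min_bout_ms, fps))
  occ <- roi_occupancy(track_mm, roi_mm, "pup", "nest", "any")
  sc <- score_retrieval(occ, labels[["carry"]], fps,
                        carry_window_s = carry_window_s,
                        max_trial_s = max_trial_s)
  behaviors <- lapply(labels, behavior_summary, fps = fps,
                      max_trial_s = max_trial_s)
  structure(list(retrieved = sc$retrieved,
                 retrieval_time_s = sc$retrieval_time_s,
                 behaviors = behaviors, labels = labels,
                 pup_nest_occupancy = occ, fps = fps),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("retrieval_result: %s (time %.1f s)\n",
              if (x$retrieved == 1L) "retrieved" else "not retrieved",
              x$retrieval_time_s))
  for (b in names(x$behaviors))
    cat(sprintf("  %-9s latency %6.1f s, duration %6.1f s, %d bout(s)\n",
                b, x$behaviors[[b]]$latency_s,
                x$behaviors[[b]]$total_duration_s,
                x$behaviors[[b]]$bout_count))
  invisible(x)
}

#' Flatten a retrieval result to a one-row data frame
#'
#' @param x A `retrieval_result`.
#' @param ... Unused.
#' @return One-row data frame with retrieval status/time and per-behavior
#'   latency, duration and count columns.
#' @export
as.data.frame.retrieval_result <- function(x, ...) {
  row <- data.frame(retrieved = x$retrieved,
                    retrieval_time_s = x$retrieval_time_s)
  for (b in names(x$behaviors)) {
    s <- x$behaviors[[b]]
    row[[paste0(b, "_latency_s")]] <- s$latency_s
    row[[paste0(b, "_duration_s")]] <- s$total_duration_s
    row[[paste0(b, "_bouts")]] <- s$bout_count
  }
  row
}
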