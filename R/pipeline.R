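#' Batch analysis of PRT trials
#'
#' Runs the full chain — read pose table, compute outlier criteria, correct
#' outliers, calibrate to mm, extract features, predict and smooth each
#' behavior, score retrieval — for every trial in a manifest. Each trial
#' uses its own fps and calibration from its metadata file (recordings vary
#' between 10 and 30 fps, so nothing is assumed global). A failure in any
#' stage marks that trial failed with the stage name and the batch
#' continues; the summary always has one row per manifest entry.
#'
#' The run is deterministic: identical manifest, bundles and parameters
#' give identical outputs.
#'
#' @param manifest Data frame with columns `trial_id`, `pose`, `roi`,
#'   `meta` (file paths per trial).
#' @param bundles Named list of `classifier_bundle`s (must include
#'   `"carry"`).
#' @param out_dir Optional directory; per-trial JSON results and the batch
#'   summary CSV are written there.
#' @param movement_factor,location_factor Outlier criteria factors.
#' @param carry_window_s Carry look-back window for [score_retrieval()].
#' @param windows_s Rolling feature windows.
#' @return List with `results` (per-trial `retrieval_result` or error
#'   condition) and `summary` (one row per trial: status, failed stage if
#'   any, retrieval and behavior columns).
#' @export
run_trial_analysis <- function(manifest, bundles, out_dir = NULL,
                               movement_factor = 2.5, location_factor = 4,
                               carry_window_s = 3,
                               windows_s = c(0.2, 0.5, 1.0)) {
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("trial_id", "pose", "roi", "meta") %in% names(manifest)))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- vector("list", nrow(manifest))
  names(results) <- manifest$trial_id
  rows <- vector("list", nrow(manifest))

  for (i in seq_len(nrow(manifest))) {
    id <- manifest$trial_id[i]
    stage <- "meta"
    res <- tryCatch({
      meta <- read_trial_meta(manifest$meta[i])
      stage <- "pose"
      track <- read_pose_table(manifest$pose[i], fps = meta$fps)
      stage <- "roi"
      roi <- read_roi(manifest$roi[i])
      stage <- "preprocess"
      crit <- compute_criteria(track, movement_factor, location_factor)
      corrected <- correct_outliers(track, crit)
      stage <- "calibrate"
      if (is.null(meta$calibration_px))
        stop("trial metadata lacks calibration_px landmarks")
      cal <- calibrate(meta$calibration_px[[1]], meta$calibration_px[[2]],
                       meta$calibration_reference_mm)
      track_mm <- to_mm(corrected$track, cal)
      roi_mm <- roi_to_mm(roi, cal)
      stage <- "score"
      out <- score_trial(track_mm, roi_mm, bundles,
                         carry_window_s = carry_window_s,
                         max_trial_s = meta$max_trial_s,
                         windows_s = windows_s)
      out$outlier_report <- corrected$report
      out
    }, error = function(e) {
      structure(list(message = conditionMessage(e), stage = stage),
                class = "trial_failure")
    })
    results[[i]] <- res
    if (inherits(res, "trial_failure")) {
      rows[[i]] <- data.frame(trial_id = id, status = "failed",
                              failed_stage = res$stage)
    } else {
      row <- cbind(data.frame(trial_id = id, status = "ok",
                              failed_stage = NA_character_),
                   as.data.frame(res))
      rows[[i]] <- row
      if (!is.null(out_dir))
        jsonlite::write_json(
          c(list(trial_id = id), as.list(as.data.frame(res))),
          file.path(out_dir, paste0(id, ".json")), auto_unbox = TRUE,
          digits = NA)
    }
  }

  all_cols <- unique(unlist(lapply(rows, names)))
  summary <- do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "batch_summary.csv"),
                     row.names = FALSE)
  list(results = results, summary = summary)
}

#' Write a simulated trial to disk in pipeline formats
#'
#' Writes the pose table, ground-truth annotations, ROI YAML and trial
#' metadata YAML of a [generate_trial()] result into a directory, and
#' returns the one-row manifest entry pointing at them.
#'
#' @param trial A [generate_trial()] result.
#' @param dir Output directory.
#' @return One-row manifest data frame (`trial_id`, `pose`, `roi`, `meta`,
#'   plus `annotations`).
#' @export
write_trial_files <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- trial$meta$trial_id
  pose <- file.path(dir, paste0(id, "_pose.csv"))
  roi <- file.path(dir, paste0(id, "_roi.yaml"))
  meta <- file.path(dir, paste0(id, "_meta.yaml"))
  ann <- file.path(dir, paste0(id, "_annotations.csv"))
  write_pose_table(trial$track, pose)
  write_roi(trial$roi, roi)
  write_trial_meta(trial$meta, meta)
  write_annotations(trial$truth$labels, ann)
  data.frame(trial_id = id, pose = pose, roi = roi, meta = meta,
             annotations = ann, stringsAsFactors = FALSE)
}
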