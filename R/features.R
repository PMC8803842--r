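#' Per-frame feature matrix for behavior classification
#'
#' Builds a deterministic, documented feature set from a corrected,
#' calibrated pose track and the trial's ROIs. The base features are:
#'
#' * `dam_nose_pup_dist`, `dam_pup_dist`: dam-nose-to-pup-centroid and
#'   centroid-to-centroid distances (mm);
#' * `dam_nest_dist`, `dam_core_dist`, `pup_nest_dist`, `pup_core_dist`:
#'   animal-centroid distances to the nest polygon centroid and the
#'   core-nest center (mm);
#' * `move_<part>`: per-part frame-to-frame displacement (mm/frame; 0 at
#'   frame 0), and `dam_move_mean` / `pup_move_mean`, the per-animal means;
#' * `dam_pup_ddist`: signed per-frame change of `dam_pup_dist` (mm/frame;
#'   negative while the dam closes in on the pup), and
#'   `dam_pup_closing_ratio`, the same change normalized by the dam's mean
#'   movement (`ddist / (dam_move_mean + 0.1)`) — a speed-invariant heading
#'   cue near -1 when closing straight in, +1 when moving away, 0 when
#'   stationary or when the pup travels with the dam;
#' * `dam_extent`, `pup_extent`: sum of pairwise within-animal part
#'   distances (body spread, mm);
#' * `dam_in_nest`, `pup_in_nest`, `dam_in_core`, `pup_in_core`: 0/1 ROI
#'   flags (`mode = "any"`).
#'
#' Each base feature additionally gets centered rolling mean, median and
#' standard deviation over the requested windows (seconds, converted to
#' frames by `round`, minimum 1 frame, so recordings at 10-30 fps remain
#' comparable); boundary frames are padded by edge replication. The result
#' is a pure function of `(track, roi, windows)`: identical inputs give
#' bit-identical output.
#'
#' @param track A corrected [pose_track()] in mm.
#' @param roi A [roi_config()] in the same (mm) frame.
#' @param windows_s Rolling-window lengths in seconds.
#' @return Data frame, one row per frame, with attribute `registry`
#'   (a data frame naming each feature and its formula).
#' @export
extract_features <- function(track, roi, windows_s = c(0.2, 0.5, 1.0)) {
  stopifnot(inherits(track, "pose_track"), inherits(roi, "roi_config"))
  if (track$unit != "mm")
    stop("track must be calibrated to mm before feature extraction")
  if (anyNA(track$x) || anyNA(track$y))
    stop("NaN in input coordinates: run outlier correction first")
  nf <- n_frames(track)
  fps <- track$fps

  dam_c <- animal_centroid(track, "dam")
  pup_c <- animal_centroid(track, "pup")
  dam_nose <- cbind(track$x[, part_col(track, "dam", "nose")],
                    track$y[, part_col(track, "dam", "nose")])
  nest_c <- polygon_centroid(roi$nest)

  dist2 <- function(p, q) sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)
  dist_pt <- function(p, q) sqrt((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2)

  feats <- list(
    dam_nose_pup_dist = dist2(dam_nose, pup_c),
    dam_pup_dist = dist2(dam_c, pup_c),
    dam_nest_dist = dist_pt(dam_c, nest_c),
    dam_core_dist = dist_pt(dam_c, roi$core_center),
    pup_nest_dist = dist_pt(pup_c, nest_c),
    pup_core_dist = dist_pt(pup_c, roi$core_center))

  reg <- data.frame(name = names(feats), formula = c(
    "euclid(dam nose, pup centroid)", "euclid(dam centroid, pup centroid)",
    "euclid(dam centroid, nest polygon centroid)",
    "euclid(dam centroid, core-nest center)",
    "euclid(pup centroid, nest polygon centroid)",
    "euclid(pup centroid, core-nest center)"), stringsAsFactors = FALSE)

  disp <- matrix(0, nf, nrow(track$parts))
  if (nf > 1L)
    disp[-1L, ] <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  for (j in seq_len(nrow(track$parts))) {
    nm <- paste0("move_", track$parts$label[j])
    feats[[nm]] <- disp[, j]
    reg <- rbind(reg, data.frame(name = nm, formula = sprintf(
      "frame displacement of %s (0 at frame 0)", track$parts$label[j])))
  }
  for (a in PRT_ANIMALS) {
    nm <- paste0(a, "_move_mean")
    feats[[nm]] <- rowMeans(disp[, animal_cols(track, a), drop = FALSE])
    reg <- rbind(reg, data.frame(name = nm, formula = paste(
      "mean frame displacement over", a, "parts")))
  }

  ddist <- c(0, diff(feats$dam_pup_dist))
  feats$dam_pup_ddist <- ddist
  reg <- rbind(reg, data.frame(name = "dam_pup_ddist", formula =
    "signed frame change of dam_pup_dist (relative speed)"))
  # speed-invariant heading cue: ~ -1 closing straight in, ~ +1 moving
  # away, ~ 0 when stationary or when the pup moves with the dam (carry)
  feats$dam_pup_closing_ratio <- ddist / (feats$dam_move_mean + 0.1)
  reg <- rbind(reg, data.frame(name = "dam_pup_closing_ratio", formula =
    "dam_pup_ddist / (dam_move_mean + 0.1 mm)"))

  for (a in PRT_ANIMALS) {
    idx <- animal_cols(track, a)
    ext <- rep(0, nf)
    for (i in seq_along(idx)[-length(idx)])
      for (k in (i + 1L):length(idx))
        ext <- ext + sqrt((track$x[, idx[i]] - track$x[, idx[k]])^2 +
                          (track$y[, idx[i]] - track$y[, idx[k]])^2)
    nm <- paste0(a, "_extent")
    feats[[nm]] <- ext
    reg <- rbind(reg, data.frame(name = nm, formula = paste(
      "sum of pairwise part distances within", a)))
  }

  for (a in PRT_ANIMALS) for (rg in c("nest", "core_nest")) {
    nm <- paste0(a, if (rg == "nest") "_in_nest" else "_in_core")
    feats[[nm]] <- as.numeric(roi_occupancy(track, roi, a, rg, "any"))
    reg <- rbind(reg, data.frame(name = nm, formula = sprintf(
      "any %s part inside %s (0/1)", a, rg)))
  }

  base_names <- names(feats)
  for (ws in windows_s) {
    w <- max(1L, as.integer(round(ws * fps)))
    for (nm in base_names) for (st in c("mean", "median", "sd")) {
      rn <- sprintf("%s_%s_%gs", nm, st, ws)
      feats[[rn]] <- roll_stat(feats[[nm]], w, st)
      reg <- rbind(reg, data.frame(name = rn, formula = sprintf(
        "rolling %s of %s, window %g s (%d frames), edge-replicated",
        st, nm, ws, w)))
    }
  }

  out <- as.data.frame(feats)
  if (anyNA(out)) stop("internal error: NA in feature matrix")
  attr(out, "registry") <- reg
  out
}

# Centered rolling statistic with edge-replication padding (internal).
roll_stat <- function(x, w, stat = c("mean", "median", "sd")) {
  stat <- match.arg(stat)
  n <- length(x)
  if (w <= 1L) return(switch(stat, mean = x, median = x, sd = rep(0, n)))
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  xp <- c(rep(x[1L], left), x, rep(x[n], right))
  E <- stats::embed(xp, w)
  switch(stat,
         mean = rowMeans(E),
         median = apply(E, 1L, stats::median),
         sd = apply(E, 1L, stats::sd))
}

#' Persist a feature matrix with its registry
#'
#' Writes the features as CSV and the feature registry (name and formula of
#' every column) as a JSON sidecar next to it.
#'
#' @param features Result of [extract_features()].
#' @param path CSV output path; the registry goes to `<path>.registry.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  reg <- attr(features, "registry")
  if (!is.null(reg))
    jsonlite::write_json(reg, paste0(path, ".registry.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
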