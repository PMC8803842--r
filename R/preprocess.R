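#' Median-based tracking outlier criteria
#'
#' Tracking errors show up as impossible movements (a part teleports between
#' frames) or impossible locations (a part far from the rest of its animal's
#' body). Both are detected against criteria scaled from the animal's own
#' size: the per-animal median of the frame-wise euclidean nose-to-spine1
#' distance, multiplied by `movement_factor` (default 2.5) for movement
#' outliers and by `location_factor` (default 4) for location outliers.
#'
#' Criteria are computed per animal so the pup's smaller body gets a
#' proportionally smaller criterion than the dam's.
#'
#' @param track A [pose_track()] (pixel units; run before calibration).
#' @param movement_factor Multiplier on the median for movement outliers.
#' @param location_factor Multiplier on the median for location outliers.
#' @return Object of class `outlier_criteria`: per animal, the median
#'   nose-spine1 distance and the two criteria, plus the factors used.
#' @export
#' @examples
#' # constant nose-spine1 distance of 10 px gives criteria (25, 40)
compute_criteria <- function(track, movement_factor = 2.5,
                             location_factor = 4) {
  stopifnot(inherits(track, "pose_track"))
  if (movement_factor <= 0 || location_factor <= 0)
    stop("factors must be positive")
  per_animal <- lapply(unique(track$parts$animal), function(a) {
    jn <- part_col(track, a, "nose")
    js <- part_col(track, a, "spine1")
    d <- sqrt((track$x[, jn] - track$x[, js])^2 +
              (track$y[, jn] - track$y[, js])^2)
    if (all(!is.finite(d))) stop("nose or spine1 missing for animal ", a)
    med <- stats::median(d[is.finite(d)])
    if (med <= 0) stop("degenerate track: zero median nose-spine1 distance ",
                       "for animal ", a)
    list(median = med, movement = med * movement_factor,
         location = med * location_factor)
  })
  names(per_animal) <- unique(track$parts$animal)
  structure(list(animals = per_animal, movement_factor = movement_factor,
                 location_factor = location_factor),
            class = "outlier_criteria")
}

#' @export
print.outlier_criteria <- function(x, ...) {
  cat("outlier_criteria (factors:", x$movement_factor, "movement,",
      x$location_factor, "location)\n")
  for (a in names(x$animals))
    cat(sprintf("  %s: median %.2f -> movement %.2f, location %.2f\n", a,
                x$animals[[a]]$median, x$animals[[a]]$movement,
                x$animals[[a]]$location))
  invisible(x)
}

#' Correct tracking outliers
#'
#' Two sequential passes over each body part, both replacing an outlying
#' coordinate with the part's last accepted location (carry-forward; no
#' look-ahead, so causality is preserved):
#'
#' 1. *Movement pass*: a part whose distance from its last accepted location
#'    exceeds the animal's movement criterion is replaced by that location.
#'    Frame 0 is always accepted.
#' 2. *Location pass*: on the movement-corrected coordinates, a part lying
#'    farther than the location criterion from at least two other parts of
#'    the same animal is replaced by its last non-outlying location. A part
#'    that is outlying at frame 0 (no prior good location) keeps its
#'    original value and is flagged in the report.
#'
#' Frame and part counts are never changed; coordinates not flagged by
#' either pass are returned bit-identical. Likelihood values are carried
#' through untouched: the quality control is purely distance-based.
#'
#' @param track A [pose_track()].
#' @param criteria An `outlier_criteria` from [compute_criteria()].
#' @return List with elements `track` (corrected [pose_track()]) and
#'   `report` (class `outlier_report`: per-part movement and location
#'   correction counts, uncorrectable flags, criteria used).
#' @export
correct_outliers <- function(track, criteria) {
  stopifnot(inherits(track, "pose_track"),
            inherits(criteria, "outlier_criteria"))
  nf <- n_frames(track)
  np <- nrow(track$parts)
  x <- track$x; y <- track$y
  mv_count <- integer(np); loc_count <- integer(np)
  uncorrectable <- integer(0)

  crit_mv <- vapply(track$parts$animal,
                    function(a) criteria$animals[[a]]$movement, 0)
  crit_loc <- vapply(track$parts$animal,
                     function(a) criteria$animals[[a]]$location, 0)

  # Pass 1: movement outliers, per part, against last accepted location.
  for (j in seq_len(np)) {
    ax <- x[1L, j]; ay <- y[1L, j]
    for (t in seq_len(nf)[-1L]) {
      if (sqrt((x[t, j] - ax)^2 + (y[t, j] - ay)^2) > crit_mv[j]) {
        x[t, j] <- ax; y[t, j] <- ay
        mv_count[j] <- mv_count[j] + 1L
      } else {
        ax <- x[t, j]; ay <- y[t, j]
      }
    }
  }

  # Pass 2: location outliers, detected on a snapshot of the pass-1 result.
  flagged <- matrix(FALSE, nf, np)
  for (a in unique(track$parts$animal)) {
    idx <- animal_cols(track, a)
    for (j in idx) {
      others <- setdiff(idx, j)
      n_far <- rowSums(
        sqrt((x[, others, drop = FALSE] - x[, j])^2 +
             (y[, others, drop = FALSE] - y[, j])^2) > crit_loc[j])
      flagged[, j] <- n_far >= 2L
    }
  }
  for (j in seq_len(np)) {
    good <- NA_integer_
    for (t in seq_len(nf)) {
      if (flagged[t, j]) {
        if (is.na(good)) {
          uncorrectable <- c(uncorrectable, j)  # keep original, flag only
        } else {
          x[t, j] <- x[good, j]; y[t, j] <- y[good, j]
          loc_count[j] <- loc_count[j] + 1L
        }
      } else {
        good <- t
      }
    }
  }

  report <- structure(
    list(parts = track$parts$label,
         movement_corrections = stats::setNames(mv_count,
                                                track$parts$label),
         location_corrections = stats::setNames(loc_count,
                                                track$parts$label),
         uncorrectable_parts = unique(track$parts$label[uncorrectable]),
         criteria = criteria),
    class = "outlier_report")
  out <- track
  out$x <- x; out$y <- y
  list(track = out, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report:",
      sum(x$movement_corrections), "movement and",
      sum(x$location_corrections), "location corrections\n")
  if (length(x$uncorrectable_parts) > 0L)
    cat("  uncorrectable at frame 0:",
        paste(x$uncorrectable_parts, collapse = ", "), "\n")
  invisible(x)
}

#' Pixel-to-millimeter calibration from a cage landmark
#'
#' The standard recording geometry uses the length between the top lids of
#' the home cage as a known landmark: a standardized distance of 265 mm.
#' The scale is `reference_mm / euclidean(a, b)` in mm per pixel.
#'
#' @param landmark_a,landmark_b Numeric `c(x, y)` pixel coordinates of the
#'   two landmark points.
#' @param reference_mm Real-world distance between the landmarks, mm.
#' @return Object of class `calibration` with `reference_px`,
#'   `reference_mm` and `scale` (mm per px).
#' @export
#' @examples
#' calibrate(c(0, 0), c(530, 0))$scale  # 0.5 mm/px
calibrate <- function(landmark_a, landmark_b, reference_mm = 265) {
  d <- sqrt(sum((as.numeric(landmark_a) - as.numeric(landmark_b))^2))
  if (!is.finite(d) || d <= 0)
    stop("calibration landmarks are coincident or invalid")
  if (reference_mm <= 0) stop("reference_mm must be positive")
  structure(list(reference_px = d, reference_mm = reference_mm,
                 scale = reference_mm / d),
            class = "calibration")
}

#' Standardize a pixel track to millimeters
#'
#' Multiplies all coordinates by the calibration scale and flips the unit to
#' mm. Likelihoods are unchanged. Applying it to a track already in mm is an
#' error (no silent double scaling).
#'
#' @param track A [pose_track()] in pixel units.
#' @param calibration A [calibrate()] result.
#' @return The track in mm.
#' @export
to_mm <- function(track, calibration) {
  stopifnot(inherits(track, "pose_track"),
            inherits(calibration, "calibration"))
  if (track$unit == "mm")
    stop("track is already in mm; refusing to scale twice")
  track$x <- track$x * calibration$scale
  track$y <- track$y * calibration$scale
  track$unit <- "mm"
  track
}

#' Optional likelihood floor filter
#'
#' Replaces coordinates whose tracking likelihood falls below `floor` by the
#' part's last confident location (carry-forward). Off by default in the
#' pipeline: the standard quality control is distance-based, and this filter
#' is an optional extra for recordings with heavy occlusion.
#'
#' @param track A [pose_track()].
#' @param floor Likelihood threshold below which a coordinate is replaced.
#' @return The filtered track.
#' @export
apply_likelihood_floor <- function(track, floor = 0.2) {
  stopifnot(inherits(track, "pose_track"))
  for (j in seq_len(nrow(track$parts))) {
    low <- track$likelihood[, j] < floor
    good_x <- track$x[1L, j]; good_y <- track$y[1L, j]
    for (t in seq_len(n_frames(track))) {
      if (low[t] && t > 1L) {
        track$x[t, j] <- good_x; track$y[t, j] <- good_y
      } else {
        good_x <- track$x[t, j]; good_y <- track$y[t, j]
      }
    }
  }
  track
}
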