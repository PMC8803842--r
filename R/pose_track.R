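# Canonical 14-part dam + pup pose configuration.
PRT_PARTS <- c("nose", "ear_left", "ear_right", "spine1", "spine2", "spine3",
               "tail_base")
PRT_ANIMALS <- c("dam", "pup")

#' Default body-part to animal mapping
#'
#' The canonical pose configuration tracks seven body parts on the dam and
#' seven on the isolated pup: nose, left/right ear, three spine points and
#' the tail base, labelled `dam_nose`, ..., `pup_tail_base`. The `nose` and
#' `spine1` parts must exist under these names for each animal because the
#' tracking quality-control criteria are defined on their distance.
#'
#' @return Named character vector mapping part label to animal
#'   (`"dam"` or `"pup"`).
#' @export
#' @examples
#' default_animal_map()
default_animal_map <- function() {
  labels <- paste(rep(PRT_ANIMALS, each = length(PRT_PARTS)), PRT_PARTS,
                  sep = "_")
  stats::setNames(rep(PRT_ANIMALS, each = length(PRT_PARTS)), labels)
}

#' Construct a pose track
#'
#' A pose track holds per-frame (x, y, likelihood) estimates for a set of
#' named body parts belonging to the dam and the pup. Frames are indexed
#' from 0; frame `t` occurs at time `t / fps` seconds. Coordinates are in
#' pixels as exported by the tracking tool until [to_mm()] converts them.
#'
#' @param x,y Numeric frames x parts matrices of coordinates.
#' @param likelihood Numeric frames x parts matrix of tracking confidences
#'   in \[0, 1\].
#' @param parts Data frame with columns `label`, `animal`, `part`, one row
#'   per tracked body part, in column order of `x`.
#' @param fps Frames per second of the recording (supplied by trial
#'   metadata; recordings vary between 10 and 30 fps).
#' @param unit Coordinate unit, `"px"` or `"mm"`.
#' @return Object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood, parts, fps, unit = c("px", "mm")) {
  unit <- match.arg(unit)
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(likelihood)))
    stop("x, y and likelihood must have identical dimensions")
  if (nrow(x) < 1L) stop("no frames: a pose track needs at least one frame")
  if (ncol(x) != nrow(parts))
    stop("parts table does not match coordinate columns")
  stopifnot(all(c("label", "animal", "part") %in% names(parts)))
  if (anyDuplicated(parts$label)) stop("duplicate body-part labels")
  if (!all(parts$animal %in% PRT_ANIMALS))
    stop("animals must be 'dam' or 'pup'")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number")
  if (anyNA(likelihood) || any(likelihood < 0 | likelihood > 1))
    stop("likelihood values must lie in [0, 1]")
  colnames(x) <- colnames(y) <- colnames(likelihood) <- parts$label
  structure(
    list(x = x, y = y, likelihood = likelihood,
         parts = as.data.frame(parts, stringsAsFactors = FALSE),
         fps = fps, unit = unit),
    class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("pose_track: %d frames, %d parts, %.6g fps, unit %s\n",
              n_frames(x), nrow(x$parts), x$fps, x$unit))
  cat(sprintf("  duration %.1f s; animals: %s\n", n_frames(x) / x$fps,
              paste(unique(x$parts$animal), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a pose track
#' @param track A `pose_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) nrow(track$x)

# Column indices of one animal's parts (internal).
animal_cols <- function(track, animal) {
  idx <- which(track$parts$animal == animal)
  if (length(idx) == 0L) stop("unknown animal: ", animal)
  idx
}

# Column index of a named part for an animal (internal).
part_col <- function(track, animal, part) {
  idx <- which(track$parts$animal == animal & track$parts$part == part)
  if (length(idx) != 1L)
    stop(sprintf("part '%s' not found (or not unique) for animal '%s'",
                 part, animal))
  idx
}

#' Per-frame centroid of an animal
#'
#' Mean x and y over the animal's tracked parts, per frame.
#'
#' @param track A `pose_track`.
#' @param animal `"dam"` or `"pup"`.
#' @return Numeric frames x 2 matrix with columns `x`, `y`.
#' @export
animal_centroid <- function(track, animal) {
  idx <- animal_cols(track, animal)
  cbind(x = rowMeans(track$x[, idx, drop = FALSE]),
        y = rowMeans(track$y[, idx, drop = FALSE]))
}
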