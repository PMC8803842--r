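#' Read a DeepLabCut-style pose table
#'
#' Parses the three-header-row tabular dialect exported by pose-estimation
#' tools: a `scorer` row, a `bodyparts` row and a `coords` row, followed by
#' one data row per frame whose first column is the frame index and whose
#' remaining columns carry `x`, `y`, `likelihood` triplets per body part.
#'
#' By default exactly the canonical 14 parts (see [default_animal_map()])
#' are expected; supplying an explicit `animal_map` covering the file's part
#' labels overrides that check, so tracks with other configurations can be
#' loaded.
#'
#' A unit tag written by [write_pose_table()] into the scorer row (e.g.
#' `prtkit:mm`) is honoured so that millimeter tracks survive a round trip;
#' plain exports are read as pixels.
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the recording (not stored in the export;
#'   must come from trial metadata).
#' @param animal_map Named character vector mapping part label to animal;
#'   `NULL` uses [default_animal_map()] and enforces the 14-part layout.
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, fps, animal_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3L) stop("malformed header: expected 3 header rows ",
                           "(scorer / bodyparts / coords), got ", nrow(raw))
  hdr <- as.character(unlist(raw[1:3, 1]))
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(tolower(hdr) != expected)
  if (length(bad) > 0L)
    stop(sprintf("malformed header row %d: expected '%s', found '%s'",
                 bad[1], expected[bad[1]], hdr[bad[1]]))
  if (nrow(raw) < 4L) stop("no frames: the data section is empty")

  bodyparts <- as.character(unlist(raw[2, -1]))
  coords <- as.character(unlist(raw[3, -1]))
  labels <- unique(bodyparts)
  for (lb in labels) {
    have <- coords[bodyparts == lb]
    if (!identical(sort(have), sort(c("x", "y", "likelihood"))))
      stop(sprintf("malformed header row 3: part '%s' must contribute ",
                   lb), "exactly the columns x, y, likelihood")
  }

  explicit_map <- !is.null(animal_map)
  if (!explicit_map) animal_map <- default_animal_map()
  if (!explicit_map && length(labels) != 14L)
    stop("configuration error: expected 14 body parts (7 dam + 7 pup), ",
         "found ", length(labels),
         "; pass an explicit animal_map to override")
  missing <- setdiff(labels, names(animal_map))
  if (length(missing) > 0L)
    stop("configuration error: no animal assigned for part(s): ",
         paste(missing, collapse = ", "))

  dat <- raw[-(1:3), -1, drop = FALSE]
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(dat)), nrow = nrow(dat)))
  if (anyNA(num)) {
    bad_cell <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: non-numeric value at frame %d (data row %d)",
                 bad_cell[1] - 1L, bad_cell[1]))
  }

  x <- num[, which(coords == "x"), drop = FALSE]
  y <- num[, which(coords == "y"), drop = FALSE]
  lik <- num[, which(coords == "likelihood"), drop = FALSE]
  ord <- match(labels, bodyparts[coords == "x"])
  x <- x[, ord, drop = FALSE]
  y <- y[, ord, drop = FALSE]
  lik <- lik[, ord, drop = FALSE]

  unit <- "px"
  scorer_val <- as.character(unlist(raw[1, -1]))[1]
  if (grepl(":mm$", scorer_val)) unit <- "mm"

  parts <- data.frame(
    label = labels,
    animal = unname(animal_map[labels]),
    part = sub("^(dam|pup)_", "", labels),
    stringsAsFactors = FALSE)
  pose_track(x, y, lik, parts, fps = fps, unit = unit)
}

#' Write a pose track in the DeepLabCut-style dialect
#'
#' Emits the three header rows (`scorer`, `bodyparts`, `coords`) and one row
#' per frame with a 0-based frame index, preserving the track's part order.
#' The coordinate unit is recorded as a suffix on the scorer value
#' (`prtkit:px` / `prtkit:mm`) so a round trip preserves it.
#'
#' @param track A [pose_track()].
#' @param path Output path.
#' @param scorer Scorer name written in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path, scorer = "prtkit") {
  stopifnot(inherits(track, "pose_track"))
  np <- nrow(track$parts)
  scorer_tag <- paste0(scorer, ":", track$unit)
  hdr1 <- c("scorer", rep(scorer_tag, 3L * np))
  hdr2 <- c("bodyparts", rep(track$parts$label, each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), np))
  dat <- matrix("", nrow = n_frames(track), ncol = 3L * np)
  for (j in seq_len(np)) {
    dat[, 3L * j - 2L] <- sprintf("%.6f", track$x[, j])
    dat[, 3L * j - 1L] <- sprintf("%.6f", track$y[, j])
    dat[, 3L * j] <- sprintf("%.6f", track$likelihood[, j])
  }
  rows <- c(paste(hdr1, collapse = ","),
            paste(hdr2, collapse = ","),
            paste(hdr3, collapse = ","),
            paste(seq_len(nrow(dat)) - 1L,
                  apply(dat, 1L, paste, collapse = ","), sep = ","))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Read frame-level behavior annotations
#'
#' An annotation file has a header row of behavior names and one row per
#' frame; every cell is 0 (behavior absent) or 1 (present).
#'
#' @param path Path to the CSV file.
#' @param n_frames Expected frame count (from the paired pose track).
#' @return Integer matrix, frames x behaviors, with behavior column names.
#' @export
read_annotations <- function(path, n_frames) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (nrow(dat) != n_frames)
    stop(sprintf("annotation length %d does not match pose track length %d",
                 nrow(dat), n_frames))
  m <- as.matrix(dat)
  bad <- which(matrix(!(m %in% c(0, 1)), nrow(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid annotation value '%s' at row %d (must be 0 or 1)",
                 m[bad[1, 1], bad[1, 2]], bad[1, 1]))
  storage.mode(m) <- "integer"
  m
}

#' Write frame-level behavior annotations
#'
#' @param labels Integer matrix or data frame of 0/1 values, one column per
#'   behavior with behavior names as column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(labels, path) {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0L, 1L))) stop("annotation values must be 0 or 1")
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}

#' Read or write trial metadata
#'
#' Trial metadata is a small YAML (or JSON) document with the trial
#' identifier, the recording frame rate, the maximum trial time (90 s in the
#' standard protocol; unretrieved trials are assigned this time), the
#' calibration reference length in millimeters (265 mm between the cage lid
#' landmarks), and optionally the two landmark pixel coordinates.
#'
#' @param path Path to the YAML file.
#' @return A list of class `trial_meta`.
#' @export
read_trial_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- yaml::read_yaml(path)
  trial_meta(trial_id = m$trial_id, fps = m$fps,
             max_trial_s = m$max_trial_s %||% 90,
             calibration_reference_mm = m$calibration_reference_mm %||% 265,
             calibration_px = m$calibration_px)
}

#' @rdname read_trial_meta
#' @param meta A `trial_meta` object.
#' @export
write_trial_meta <- function(meta, path) {
  stopifnot(inherits(meta, "trial_meta"))
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

#' @rdname read_trial_meta
#' @param trial_id Trial identifier string.
#' @param fps Frames per second (positive).
#' @param max_trial_s Maximum trial duration in seconds.
#' @param calibration_reference_mm Real-world length of the calibration
#'   landmark pair, mm.
#' @param calibration_px Optional list of two `c(x, y)` pixel points marking
#'   the calibration landmarks.
#' @export
trial_meta <- function(trial_id, fps, max_trial_s = 90,
                       calibration_reference_mm = 265,
                       calibration_px = NULL) {
  if (is.null(fps) || fps <= 0) stop("fps must be positive")
  if (max_trial_s <= 0) stop("max_trial_s must be positive")
  structure(list(trial_id = as.character(trial_id), fps = fps,
                 max_trial_s = max_trial_s,
                 calibration_reference_mm = calibration_reference_mm,
                 calibration_px = calibration_px),
            class = "trial_meta")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
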