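#' Nest and core-nest regions of interest
#'
#' Each trial video gets two fixed regions of interest: the *nest*, a simple
#' polygon enclosing the entire nesting site, and the *core nest*, a circle
#' enclosing only the spot where the pups lie. Both are defined in the
#' video's pixel coordinate frame and can be rescaled to mm with
#' [roi_to_mm()]. ROIs are fixed for the whole trial; a nest that shifts
#' during the trial is a known limitation of the protocol, not modelled.
#'
#' @param nest Numeric n x 2 matrix of polygon vertices (ordered, >= 3,
#'   non-self-intersecting).
#' @param core_center Numeric `c(x, y)` circle center.
#' @param core_radius Positive circle radius.
#' @param trial_id Optional trial/video identifier.
#' @return Object of class `roi_config`.
#' @export
roi_config <- function(nest, core_center, core_radius, trial_id = NULL) {
  nest <- as.matrix(nest)
  if (ncol(nest) != 2L || nrow(nest) < 3L)
    stop("nest polygon needs >= 3 (x, y) vertices")
  if (polygon_area(nest) <= 0)
    stop("degenerate nest polygon: vertices are collinear")
  if (self_intersects(nest))
    stop("nest polygon is self-intersecting")
  core_center <- as.numeric(core_center)
  if (length(core_center) != 2L || !all(is.finite(core_center)))
    stop("core_center must be a finite (x, y) point")
  if (!is.numeric(core_radius) || core_radius <= 0)
    stop("core_radius must be positive")
  structure(list(nest = unname(nest), core_center = core_center,
                 core_radius = core_radius, trial_id = trial_id),
            class = "roi_config")
}

# Shoelace area (absolute), internal.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Area centroid of a simple polygon (shoelace form), internal.
polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# O(n^2) proper-crossing check between non-adjacent edges, internal.
self_intersects <- function(p) {
  n <- nrow(p)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1L else i + 1L, ])
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  for (i in seq_len(n - 2L)) for (k in (i + 2L):n) {
    if (i == 1L && k == n) next  # adjacent through the closing edge
    s1 <- seg(i); s2 <- seg(k)
    if (orient(s1[1, ], s1[2, ], s2[1, ]) *
        orient(s1[1, ], s1[2, ], s2[2, ]) < 0 &&
        orient(s2[1, ], s2[2, ], s1[1, ]) *
        orient(s2[1, ], s2[2, ], s1[2, ]) < 0) return(TRUE)
  }
  FALSE
}

#' Point-in-polygon test
#'
#' Vectorized containment test; points on the polygon boundary count as
#' inside (the inclusive convention is documented because ROI edges matter
#' for retrieval scoring near the nest boundary).
#'
#' @param points Numeric n x 2 matrix (or length-2 vector) of points.
#' @param polygon Numeric m x 2 vertex matrix of a simple polygon.
#' @return Logical vector of length n.
#' @export
point_in_polygon <- function(points, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || polygon_area(polygon) <= 0)
    stop("degenerate polygon")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  pracma::inpolygon(points[, 1], points[, 2],
                    polygon[, 1], polygon[, 2], boundary = TRUE)
}

#' Point-in-circle test
#'
#' Points at distance exactly equal to the radius count as inside.
#'
#' @param points Numeric n x 2 matrix (or length-2 vector).
#' @param center Numeric `c(x, y)`.
#' @param radius Positive radius.
#' @return Logical vector of length n.
#' @export
point_in_circle <- function(points, center, radius) {
  if (radius <= 0) stop("radius must be positive")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2 <= radius^2
}

#' Per-frame ROI occupancy of an animal
#'
#' For each frame, tests whether the animal's body parts lie inside the
#' chosen region. `mode = "any"` (the retrieval rule: at least one pup body
#' part inside the nest) marks a frame occupied if any part is inside;
#' `mode = "all"` requires every part inside.
#'
#' @param track A [pose_track()]; must share units and coordinate frame
#'   with `roi`.
#' @param roi A [roi_config()].
#' @param animal `"dam"` or `"pup"`.
#' @param region `"nest"` (polygon) or `"core_nest"` (circle).
#' @param mode `"any"` or `"all"`.
#' @return Logical vector, one element per frame.
#' @export
roi_occupancy <- function(track, roi, animal = c("pup", "dam"),
                          region = c("nest", "core_nest"),
                          mode = c("any", "all")) {
  stopifnot(inherits(track, "pose_track"), inherits(roi, "roi_config"))
  animal <- match.arg(animal)
  region <- match.arg(region)
  mode <- match.arg(mode)
  idx <- animal_cols(track, animal)
  inside <- vapply(idx, function(j) {
    pts <- cbind(track$x[, j], track$y[, j])
    if (region == "nest") point_in_polygon(pts, roi$nest)
    else point_in_circle(pts, roi$core_center, roi$core_radius)
  }, logical(n_frames(track)))
  if (n_frames(track) == 1L) inside <- matrix(inside, nrow = 1L)
  if (mode == "any") rowSums(inside) > 0L else rowSums(inside) == length(idx)
}

#' Rescale an ROI configuration to millimeters
#'
#' @param roi A [roi_config()] in pixels.
#' @param calibration A [calibrate()] result.
#' @return The ROI with all coordinates and the radius multiplied by the
#'   calibration scale.
#' @export
roi_to_mm <- function(roi, calibration) {
  stopifnot(inherits(roi, "roi_config"), inherits(calibration, "calibration"))
  roi_config(roi$nest * calibration$scale,
             roi$core_center * calibration$scale,
             roi$core_radius * calibration$scale,
             trial_id = roi$trial_id)
}

#' Read/write an ROI configuration as YAML
#'
#' The on-disk format is `nest: [[x, y], ...]` plus
#' `core_nest: {center: [x, y], radius: r}`.
#'
#' @param path Path to the YAML file.
#' @return A [roi_config()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  nest <- do.call(rbind, lapply(y$nest, as.numeric))
  roi_config(nest, as.numeric(y$core_nest$center), y$core_nest$radius,
             trial_id = y$trial_id)
}

#' @rdname read_roi
#' @param roi A [roi_config()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_config"))
  yaml::write_yaml(
    list(trial_id = roi$trial_id,
         nest = lapply(seq_len(nrow(roi$nest)),
                       function(i) as.numeric(roi$nest[i, ])),
         core_nest = list(center = as.numeric(roi$core_center),
                          radius = roi$core_radius)),
    path)
  invisible(path)
}
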