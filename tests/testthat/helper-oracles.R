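# Independent oracles, deliberately written as naive scalar algorithms so
# they share no code path with the implementation they check.

# Even-odd ray casting, one point at a time.
ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Random convex polygon (hull of uniform points), vertices in hull order.
random_convex_polygon <- function(n_pts = 8, lim = 10) {
  repeat {
    pts <- cbind(stats::runif(n_pts, -lim, lim),
                 stats::runif(n_pts, -lim, lim))
    h <- grDevices::chull(pts)
    if (length(h) >= 3) return(pts[h, , drop = FALSE])
  }
}

# f1 of the present class, recomputed from first principles.
naive_f1 <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  prec <- if (sum(pred == 1) == 0) 0 else tp / sum(pred == 1)
  rec <- if (sum(truth == 1) == 0) 0 else tp / sum(truth == 1)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
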