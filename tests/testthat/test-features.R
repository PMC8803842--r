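mm_track <- function(track) to_mm(track, calibrate(c(0, 0), c(265, 0)))
square_roi <- function() roi_config(rbind(c(0, 0), c(60, 0), c(60, 60),
                                          c(0, 60)), c(30, 30), 10)

test_that("stationary animals yield exactly zero movement features", {
  f <- extract_features(mm_track(blank_track(n = 20)), square_roi())
  move_cols <- grep("^move_|_move_mean$|dam_pup_ddist", names(f),
                    value = TRUE)
  expect_true(all(f[move_cols] == 0))
  expect_identical(nrow(f), 20L)
  expect_false(anyNA(f))
  expect_identical(anyDuplicated(names(f)), 0L)
})

test_that("a (3,4) mm centroid step gives mean movement 5 mm/frame", {
  tr <- blank_track(n = 2)
  dam <- which(tr$parts$animal == "dam")
  tr$x[2, dam] <- tr$x[2, dam] + 3
  tr$y[2, dam] <- tr$y[2, dam] + 4
  f <- extract_features(mm_track(tr), square_roi())
  expect_equal(f$dam_move_mean, c(0, 5))
  expect_equal(f$pup_move_mean, c(0, 0))
})

test_that("every feature column matches a straight-line recomputation", {
  tr <- mm_track(wander_track(n = 50, seed = 3))
  roi <- square_roi()
  f <- extract_features(tr, roi, windows_s = c(0.2, 0.5, 1.0))

  dam <- which(tr$parts$animal == "dam")
  pup <- which(tr$parts$animal == "pup")
  n <- 50
  exp_base <- list()
  cx <- function(idx, t) mean(tr$x[t, idx]); cy <- function(idx, t)
    mean(tr$y[t, idx])
  nose <- which(tr$parts$label == "dam_nose")
  nest_c <- c(30, 30)  # area centroid of the square
  for (t in 1:n) {
    dc <- c(cx(dam, t), cy(dam, t)); pc <- c(cx(pup, t), cy(pup, t))
    exp_base$dam_nose_pup_dist[t] <-
      sqrt((tr$x[t, nose] - pc[1])^2 + (tr$y[t, nose] - pc[2])^2)
    exp_base$dam_pup_dist[t] <- sqrt(sum((dc - pc)^2))
    exp_base$dam_nest_dist[t] <- sqrt(sum((dc - nest_c)^2))
    exp_base$dam_core_dist[t] <- sqrt(sum((dc - c(30, 30))^2))
    exp_base$pup_nest_dist[t] <- sqrt(sum((pc - nest_c)^2))
    exp_base$pup_core_dist[t] <- sqrt(sum((pc - c(30, 30))^2))
  }
  for (j in seq_len(14)) {
    nm <- paste0("move_", tr$parts$label[j])
    exp_base[[nm]] <- c(0, sqrt(diff(tr$x[, j])^2 + diff(tr$y[, j])^2))
  }
  exp_base$dam_move_mean <-
    rowMeans(sapply(dam, function(j) exp_base[[paste0("move_",
                                            tr$parts$label[j])]]))
  exp_base$pup_move_mean <-
    rowMeans(sapply(pup, function(j) exp_base[[paste0("move_",
                                            tr$parts$label[j])]]))
  exp_base$dam_pup_ddist <- c(0, diff(exp_base$dam_pup_dist))
  exp_base$dam_pup_closing_ratio <- exp_base$dam_pup_ddist /
    (exp_base$dam_move_mean + 0.1)
  for (an in c("dam", "pup")) {
    idx <- if (an == "dam") dam else pup
    ext <- numeric(n)
    for (t in 1:n) {
      s <- 0
      for (i in seq_along(idx)) for (k in seq_along(idx))
        if (i < k) s <- s + sqrt((tr$x[t, idx[i]] - tr$x[t, idx[k]])^2 +
                                 (tr$y[t, idx[i]] - tr$y[t, idx[k]])^2)
      ext[t] <- s
    }
    exp_base[[paste0(an, "_extent")]] <- ext
  }
  for (an in c("dam", "pup")) {
    idx <- if (an == "dam") dam else pup
    in_nest <- in_core <- numeric(n)
    for (t in 1:n) {
      xs <- tr$x[t, idx]; ys <- tr$y[t, idx]
      in_nest[t] <- as.numeric(any(xs >= 0 & xs <= 60 & ys >= 0 &
                                   ys <= 60))
      in_core[t] <- as.numeric(any((xs - 30)^2 + (ys - 30)^2 <= 100))
    }
    exp_base[[paste0(an, "_in_nest")]] <- in_nest
    exp_base[[paste0(an, "_in_core")]] <- in_core
  }

  for (nm in names(exp_base))
    expect_equal(f[[nm]], exp_base[[nm]], tolerance = 1e-10, label = nm)

  # rolling statistics: naive windowed recomputation with edge replication
  naive_roll <- function(x, w, fun) {
    left <- (w - 1) %/% 2; right <- w - 1 - left
    xp <- c(rep(x[1], left), x, rep(x[length(x)], right))
    vapply(seq_along(x), function(i) fun(xp[i:(i + w - 1)]), 0)
  }
  fps <- tr$fps
  for (ws in c(0.2, 0.5, 1.0)) {
    w <- max(1, round(ws * fps))
    for (nm in c("dam_pup_dist", "move_dam_nose", "pup_in_nest")) {
      expect_equal(f[[sprintf("%s_mean_%gs", nm, ws)]],
                   naive_roll(exp_base[[nm]], w, mean), tolerance = 1e-10)
      expect_equal(f[[sprintf("%s_median_%gs", nm, ws)]],
                   naive_roll(exp_base[[nm]], w, median), tolerance = 1e-10)
      expect_equal(f[[sprintf("%s_sd_%gs", nm, ws)]],
                   naive_roll(exp_base[[nm]], w,
                              function(v) if (length(v) > 1) sd(v) else 0),
                   tolerance = 1e-10)
    }
  }
})

test_that("features are translation invariant and a pure function", {
  tr <- mm_track(wander_track(n = 30, seed = 9))
  roi <- square_roi()
  f1 <- extract_features(tr, roi)
  # translate track and ROI together by (17, -4) mm
  tr2 <- tr; tr2$x <- tr2$x + 17; tr2$y <- tr2$y - 4
  roi2 <- roi_config(roi$nest + rep(c(17, -4), each = 4),
                     roi$core_center + c(17, -4), roi$core_radius)
  f2 <- extract_features(tr2, roi2)
  expect_equal(f2, f1, tolerance = 1e-9)
  # purity: identical inputs give identical output
  expect_identical(extract_features(tr, roi), f1)
})

test_that("feature extraction insists on corrected mm input", {
  expect_error(extract_features(blank_track(5), square_roi()), "mm")
  tr <- mm_track(blank_track(5))
  tr$x[2, 3] <- NA
  expect_error(extract_features(tr, square_roi()), "NaN|preprocess|correction")
})
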