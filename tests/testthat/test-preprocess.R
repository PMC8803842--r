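test_that("outlier criteria are per-animal medians times the factors", {
  # constant nose-spine1 distance of 10 px -> criteria (25, 40)
  tr <- blank_track(n = 5, nose_spine1 = 10)
  crit <- compute_criteria(tr)
  expect_equal(crit$animals$dam$movement, 25)
  expect_equal(crit$animals$dam$location, 40)
  expect_equal(crit$animals$pup$movement, 25)

  # distances {3, 4, 5, 100} -> median 4.5 -> (11.25, 18.0)
  tr2 <- blank_track(n = 4)
  jn <- which(tr2$parts$label == "dam_nose")
  js <- which(tr2$parts$label == "dam_spine1")
  tr2$x[, jn] <- tr2$x[, js] + c(3, 4, 5, 100)
  tr2$y[, jn] <- tr2$y[, js]
  crit2 <- compute_criteria(tr2)
  expect_equal(crit2$animals$dam$movement, 11.25)
  expect_equal(crit2$animals$dam$location, 18)

  # factors are configurable
  crit3 <- compute_criteria(tr, movement_factor = 1, location_factor = 2)
  expect_equal(crit3$animals$dam$movement, 10)
  expect_equal(crit3$animals$dam$location, 20)

  # degenerate zero-median track errors
  tr0 <- tr
  tr0$x[, jn] <- tr0$x[, js]; tr0$y[, jn] <- tr0$y[, js]
  expect_error(compute_criteria(tr0), "degenerate")
})

test_that("movement outliers snap back to the last accepted location", {
  tr <- blank_track(n = 10)
  crit <- compute_criteria(tr)

  # clean track: output identical, report all zeros
  res <- correct_outliers(tr, crit)
  expect_identical(res$track$x, tr$x)
  expect_identical(res$track$y, tr$y)
  expect_identical(sum(res$report$movement_corrections), 0L)
  expect_identical(sum(res$report$location_corrections), 0L)

  # single-frame teleport by 10x criterion at frame 5 (0-based)
  jn <- which(tr$parts$label == "dam_nose")
  jump <- tr
  jump$x[6, jn] <- jump$x[6, jn] + 10 * crit$animals$dam$movement
  res2 <- correct_outliers(jump, crit)
  expect_equal(res2$track$x[6, jn], tr$x[5, jn])
  expect_equal(res2$track$y[6, jn], tr$y[5, jn])
  expect_identical(unname(res2$report$movement_corrections["dam_nose"]), 1L)
  # untouched coordinates are bit-identical
  expect_identical(res2$track$x[-6, ], tr$x[-6, ])
  expect_identical(res2$track$x[6, -jn], tr$x[6, -jn])
})

test_that("location outliers far from >= 2 same-animal parts are replaced", {
  tr <- blank_track(n = 10)
  crit <- compute_criteria(tr)  # movement 25, location 40
  jn <- which(tr$parts$label == "dam_nose")
  # +24 px stays under the movement criterion but puts the nose > 40 px
  # from dam spine3 and tail_base for 3 frames
  shifted <- tr
  shifted$x[4:6, jn] <- shifted$x[4:6, jn] + 24
  res <- correct_outliers(shifted, crit)
  expect_identical(unname(res$report$movement_corrections["dam_nose"]), 0L)
  expect_identical(unname(res$report$location_corrections["dam_nose"]), 3L)
  expect_equal(res$track$x[4:6, jn], tr$x[4:6, jn])  # restored
})

test_that("correction is idempotent and bounds accepted displacements", {
  for (seed in 1:3) {
    tr <- generate_trial(random_scenario(seed, "retrieve"))$track
    noisy <- inject_tracking_noise(tr, jump_rate = 0.01,
                                   jump_magnitude_factor = 4,
                                   seed = seed + 50)$track
    crit <- compute_criteria(noisy)
    res1 <- correct_outliers(noisy, crit)
    # movement displacements measured against accepted predecessors stay
    # within the criterion
    worst_excess <- 0
    for (j in seq_len(nrow(res1$track$parts))) {
      cm <- crit$animals[[res1$track$parts$animal[j]]]$movement
      ax <- res1$track$x[1, j]; ay <- res1$track$y[1, j]
      for (t in 2:n_frames(res1$track)) {
        d <- sqrt((res1$track$x[t, j] - ax)^2 +
                  (res1$track$y[t, j] - ay)^2)
        if (d <= cm) { ax <- res1$track$x[t, j]; ay <- res1$track$y[t, j] }
        worst_excess <- max(worst_excess, d - cm)
      }
    }
    expect_lte(worst_excess, 1e-9)
    # second application with the same criteria makes zero corrections
    res2 <- correct_outliers(res1$track, crit)
    expect_identical(sum(res2$report$movement_corrections) +
                     sum(res2$report$location_corrections), 0L)
    expect_identical(res2$track$x, res1$track$x)
  }
})

test_that("calibration and mm standardization follow the landmark scale", {
  expect_equal(calibrate(c(0, 0), c(530, 0))$scale, 0.5)
  expect_equal(calibrate(c(100, 50), c(100, 315))$scale, 1.0)
  expect_error(calibrate(c(5, 5), c(5, 5)), "coincident")

  tr <- blank_track(n = 4)
  cal1 <- calibrate(c(0, 0), c(265, 0))  # scale 1.0
  mm1 <- to_mm(tr, cal1)
  expect_equal(mm1$x, tr$x)
  expect_identical(mm1$unit, "mm")
  expect_error(to_mm(mm1, cal1), "already in mm")

  cal <- calibrate(c(0, 0), c(530, 0))  # scale 0.5
  tr$x[1, 1] <- 100; tr$y[1, 1] <- 40
  mm <- to_mm(tr, cal)
  expect_equal(unname(mm$x[1, 1]), 50)
  expect_equal(unname(mm$y[1, 1]), 20)
  expect_equal(mm$likelihood, tr$likelihood)

  # any inter-point distance equals px distance x scale (random pairs)
  set.seed(7)
  w <- wander_track(n = 30, seed = 7)
  wmm <- to_mm(w, cal)
  for (k in 1:20) {
    i <- sample(30, 1); j1 <- sample(14, 1); j2 <- sample(14, 1)
    dpx <- sqrt((w$x[i, j1] - w$x[i, j2])^2 + (w$y[i, j1] - w$y[i, j2])^2)
    dmm <- sqrt((wmm$x[i, j1] - wmm$x[i, j2])^2 +
                (wmm$y[i, j1] - wmm$y[i, j2])^2)
    expect_equal(dmm, dpx * cal$scale)
  }
})
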