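test_that("idle-only scenarios produce no behavior and no retrieval", {
  scn <- prt_scenario(seed = 2, trial_s = 30,
                      episodes = data.frame(behavior = "idle", start_s = 0,
                                            end_s = 30))
  tr <- generate_trial(scn)
  expect_true(all(tr$truth$labels == 0L))
  expect_false(any(roi_occupancy(tr$track, tr$roi, "pup", "nest", "any")))
  expect_identical(tr$truth$retrieved, 0L)
  expect_equal(tr$truth$retrieval_time_s, 30)
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_trial(short_scenario(12, trial_s = 20))
  b <- generate_trial(short_scenario(12, trial_s = 20))
  expect_identical(a$track$x, b$track$x)
  expect_identical(a$track$likelihood, b$track$likelihood)
  expect_identical(a$truth, b$truth)
  c <- generate_trial(short_scenario(13, trial_s = 20))
  expect_false(identical(a$track$x, c$track$x))
})

test_that("labels and kinematics are mutually consistent", {
  tr <- cached("synth_consistency", generate_trial(prt_scenario(seed = 4)))
  scn <- tr$scenario
  scale <- 0.5
  coupling_px <- scn$coupling_mm / scale
  nose <- cbind(tr$track$x[, 1], tr$track$y[, 1])  # dam_nose is part 1
  pup_c <- animal_centroid(tr$track, "pup")
  d <- sqrt(rowSums((nose - pup_c)^2))

  # carry frames: dam nose within the coupling distance of the pup centroid
  carry <- tr$truth$labels[, "carry"] == 1L
  expect_true(any(carry))
  expect_lte(max(d[carry]), coupling_px * 1.05)

  # approach frames: dam-pup distance decreases on average over 1 s windows
  app <- which(tr$truth$labels[, "approach"] == 1L)
  w <- tr$track$fps
  dam_c <- animal_centroid(tr$track, "dam")
  dd <- sqrt(rowSums((dam_c - pup_c)^2))
  inner <- app[app + w <= max(app)]
  expect_true(all(dd[inner + w] < dd[inner]))

  # the truth retrieval frame is the first pup-in-nest occupancy frame
  occ <- roi_occupancy(tr$track, tr$roi, "pup", "nest", "any")
  expect_identical(tr$truth$retrieval_frame, which(occ)[1] - 1L)
})

test_that("ground truth equals the scoring rule on noise-free inputs", {
  for (seed in c(6, 7)) for (type in c("retrieve", "no_retrieve",
                                       "nest_shift")) {
    tr <- generate_trial(random_scenario(seed, type))
    occ <- roi_occupancy(tr$track, tr$roi, "pup", "nest", "any")
    sc <- score_retrieval(occ, tr$truth$labels[, "carry"], tr$track$fps,
                          max_trial_s = tr$scenario$trial_s)
    expect_identical(sc$retrieved, tr$truth$retrieved)
    expect_equal(sc$retrieval_time_s, tr$truth$retrieval_time_s)
  }
})

test_that("injected noise follows the requested rates and is registered", {
  tr <- cached("synth_consistency", generate_trial(prt_scenario(seed = 4)))
  clean <- inject_tracking_noise(tr$track, jump_rate = 0, seed = 1)
  expect_identical(clean$track$x, tr$track$x)
  expect_identical(nrow(clean$registry), 0L)

  noisy <- inject_tracking_noise(tr$track, jump_rate = 0.01,
                                 jump_magnitude_factor = 3,
                                 occlusion_rate = 0.02, seed = 2)
  # binomial expectation: 900 x 14 x 0.01 = 126, within 3 sigma
  n <- nrow(noisy$registry)
  expect_gt(n, 126 - 3 * sqrt(126 * 0.99))
  expect_lt(n, 126 + 3 * sqrt(126 * 0.99))
  # every injection displaced the part by the requested magnitude
  jj <- match(noisy$registry$part, tr$track$parts$label)
  moved <- sqrt((noisy$track$x[cbind(noisy$registry$frame + 1, jj)] -
                 noisy$registry$true_x)^2 +
                (noisy$track$y[cbind(noisy$registry$frame + 1, jj)] -
                 noisy$registry$true_y)^2)
  crit <- compute_criteria(tr$track)
  mv <- vapply(tr$track$parts$animal[jj],
               function(a) crit$animals[[a]]$movement, 0)
  expect_equal(unname(moved), unname(3 * mv), tolerance = 1e-6)
  # occlusions drop likelihood below 0.2 somewhere
  expect_gt(sum(noisy$track$likelihood < 0.2), 0)
  expect_error(inject_tracking_noise(tr$track, jump_rate = 2), "rates")
})

test_that("a carry scripted without approach warns but still generates", {
  scn_expr <- quote(prt_scenario(seed = 1, trial_s = 30, episodes =
    data.frame(behavior = "carry", start_s = 5, end_s = 25)))
  expect_warning(eval(scn_expr), "without a prior approach")
  scn <- suppressWarnings(eval(scn_expr))
  tr <- generate_trial(scn)
  expect_identical(n_frames(tr$track), 300L)
})
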