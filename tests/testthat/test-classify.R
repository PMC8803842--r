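# Small separable classification problem used across blocks.
separable_data <- function(n = 400, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- data.frame(f1 = y * 5 + rnorm(n, 0, 0.1),
                  f2 = rnorm(n), f3 = runif(n))
  list(X = X, y = y)
}

test_that("undersampling keeps all present frames and is seed-stable", {
  labels <- rep(c(1L, 0L), c(100, 1800))
  idx <- undersample_majority(labels, ratio = 8.5, seed = 3)
  expect_length(idx, 950)                       # 100 present + 850 absent
  expect_true(all(which(labels == 1L) %in% idx))
  expect_identical(idx, undersample_majority(labels, 8.5, seed = 3))
  expect_false(identical(idx, undersample_majority(labels, 8.5, seed = 4)))
  expect_error(undersample_majority(labels, ratio = 50, seed = 1),
               "5000.*1800|1800")
  expect_error(undersample_majority(rep(1L, 5), 2, 1), "both classes")
})

test_that("threshold selection maximizes f1 with lowest-tie breaking", {
  # probabilities equal to the labels: any positive threshold is perfect,
  # the lowest candidate (0.01) is returned
  labels <- rep(c(0L, 1L), 50)
  thr <- select_threshold(as.numeric(labels), labels)
  expect_equal(thr, 0.01)
  expect_equal(naive_f1(as.integer(as.numeric(labels) >= thr), labels), 1)

  # a 0.001 brute-force grid never beats the returned threshold
  set.seed(11)
  for (rep in 1:5) {
    p <- runif(200)
    y <- as.integer(runif(200) < p)  # noisy but informative
    thr <- select_threshold(p, y)
    f_sel <- naive_f1(as.integer(p >= thr), y)
    grid <- seq(0.001, 0.999, by = 0.001)
    f_grid <- vapply(grid, function(t) naive_f1(as.integer(p >= t), y), 0)
    expect_gte(f_sel, max(f_grid) - 1e-12)
  }
  expect_error(select_threshold(runif(5), rep(0L, 5)), "no positive")
})

test_that("forest training honours the protocol defaults and seed", {
  d <- separable_data()
  res <- train_forest(d$X, d$y, behavior = "toy", seed = 7,
                      num_trees = 2000L)
  expect_identical(res$bundle$num_trees, 2000L)
  expect_equal(res$bundle$model$num.trees, 2000)
  expect_identical(res$bundle$seed, 7)
  expect_length(res$holdout$index, 100)       # 25% of 400
  expect_equal(res$holdout$f1, 1)             # separable case
  # fixed seed -> identical predictions across two runs
  res2 <- train_forest(d$X, d$y, behavior = "toy", seed = 7,
                       num_trees = 2000L)
  expect_identical(predict_frames(res$bundle, d$X),
                   predict_frames(res2$bundle, d$X))
  expect_error(train_forest(d$X, rep(0L, 400), seed = 1), "single class")
})

test_that("frame prediction thresholds probabilities inclusively", {
  d <- separable_data()
  res <- train_forest(d$X, d$y, behavior = "toy", seed = 7,
                      num_trees = 200L)
  b <- res$bundle
  p <- prtkit:::ranger_prob(b$model, d$X)
  # agreement with manual thresholding, including p == threshold -> 1
  b$threshold <- 0.5
  expect_identical(predict_frames(b, d$X), as.integer(p >= 0.5))
  b$threshold <- max(p)  # boundary: probability equal to threshold is 1
  expect_identical(sum(predict_frames(b, d$X)), sum(p >= max(p)))
  # registry mismatch is an error
  X2 <- d$X; names(X2)[2] <- "other"
  expect_error(predict_frames(b, X2), "registry")
})

test_that("minimum-bout smoothing removes short runs only", {
  # fps 10, 500 ms -> 5 frames: a run of 4 is removed, a run of 5 kept
  labels <- c(rep(0L, 3), rep(1L, 4), rep(0L, 3), rep(1L, 5), 0L)
  out <- enforce_min_bout(labels, 500, fps = 10)
  expect_identical(out, c(rep(0L, 10), rep(1L, 5), 0L))
  expect_identical(enforce_min_bout(rep(0L, 20), 500, 10), rep(0L, 20))
  # idempotent and never creates 1s, on random vectors
  set.seed(5)
  for (rep in 1:20) {
    v <- as.integer(runif(100) < 0.4)
    s1 <- enforce_min_bout(v, 300, 10)
    expect_true(all(s1 <= v))
    expect_identical(enforce_min_bout(s1, 300, 10), s1)
  }
  # a minimum bout of 0 ms never removes anything
  v <- as.integer(runif(50) < 0.5)
  expect_identical(enforce_min_bout(v, 0, 10), v)
})

test_that("bout encoding round-trips run-length structure", {
  expect_identical(nrow(labels_to_bouts(c(0L, 0L, 0L))), 0L)
  b <- labels_to_bouts(c(0L, 1L, 1L, 0L, 1L))
  expect_equal(b$start_frame, c(1, 4))
  expect_equal(b$end_frame, c(2, 4))
  expect_identical(bouts_to_labels(b, 5), c(0L, 1L, 1L, 0L, 1L))
  set.seed(2)
  for (rep in 1:10) {
    v <- as.integer(runif(60) < 0.5)
    expect_identical(bouts_to_labels(labels_to_bouts(v), 60), v)
  }
  b2 <- labels_to_bouts(c(1L, 1L, 0L), fps = 10)
  expect_equal(b2$duration_ms, 200)
})

test_that("classifier bundles survive a save/load round trip", {
  d <- separable_data(n = 100)
  res <- train_forest(d$X, d$y, behavior = "toy", seed = 3,
                      num_trees = 50L, min_bout_ms = 200)
  dir <- withr::local_tempdir()
  save_bundle(res$bundle, file.path(dir, "toy"))
  back <- load_bundle(file.path(dir, "toy"))
  expect_identical(back$behavior, "toy")
  expect_equal(back$threshold, res$bundle$threshold)
  expect_equal(back$min_bout_ms, 200)
  expect_identical(back$feature_names, res$bundle$feature_names)
  expect_identical(predict_frames(back, d$X),
                   predict_frames(res$bundle, d$X))
})
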