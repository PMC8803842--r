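# Hand-built tracks with controlled geometry for unit tests.

# Both animals share the same part offsets so each animal's nose-spine1
# distance is exactly `nose_spine1` px; spine3/tail_base sit far enough back
# that a modest nose displacement can become a location outlier without
# tripping the movement criterion.
test_part_offsets <- function(nose_spine1 = 10) rbind(
  nose = c(nose_spine1, 0), ear_left = c(6, 3), ear_right = c(6, -3),
  spine1 = c(0, 0), spine2 = c(-2, 0), spine3 = c(-20, 0),
  tail_base = c(-28, 0))

test_parts_df <- function() data.frame(
  label = paste(rep(c("dam", "pup"), each = 7),
                rownames(test_part_offsets()), sep = "_"),
  animal = rep(c("dam", "pup"), each = 7),
  part = rep(rownames(test_part_offsets()), 2),
  stringsAsFactors = FALSE)

# Static track: dam anchored at (100, 100), pup at (400, 300).
blank_track <- function(n = 10, fps = 10, nose_spine1 = 10) {
  offs <- test_part_offsets(nose_spine1)
  x <- matrix(rep(c(100 + offs[, 1], 400 + offs[, 1]), each = n), n, 14)
  y <- matrix(rep(c(100 + offs[, 2], 300 + offs[, 2]), each = n), n, 14)
  pose_track(x, y, matrix(1, n, 14), test_parts_df(), fps = fps)
}

# Random smooth wandering track (small per-frame steps), for properties.
wander_track <- function(n = 50, fps = 10, seed = 1, step = 0.5) {
  set.seed(seed)
  offs <- test_part_offsets()
  base <- function(cx, cy) {
    px <- cx + cumsum(c(0, stats::rnorm(n - 1, 0, step)))
    py <- cy + cumsum(c(0, stats::rnorm(n - 1, 0, step)))
    list(x = outer(px, offs[, 1], "+") +
           matrix(stats::rnorm(n * 7, 0, 0.1), n, 7),
         y = outer(py, offs[, 2], "+") +
           matrix(stats::rnorm(n * 7, 0, 0.1), n, 7))
  }
  d <- base(100, 100); p <- base(400, 300)
  pose_track(cbind(d$x, p$x), cbind(d$y, p$y), matrix(1, n, 14),
             test_parts_df(), fps = fps)
}

# Memoized heavy fixtures shared across test files.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Short trial with a single approach episode, for fast I/O-level tests.
short_scenario <- function(seed, trial_s = 10, fps = 10)
  prt_scenario(seed = seed, trial_s = trial_s, fps = fps,
               episodes = data.frame(behavior = "approach", start_s = 1,
                                     end_s = min(6, trial_s - 1)))

synthetic_batch <- function(seeds, types) {
  stopifnot(length(seeds) == length(types))
  lapply(seq_along(seeds), function(i)
    generate_trial(random_scenario(seeds[i], types[i])))
}

trial_features <- function(trial) {
  cal <- calibrate(trial$meta$calibration_px[[1]],
                   trial$meta$calibration_px[[2]],
                   trial$meta$calibration_reference_mm)
  extract_features(to_mm(trial$track, cal), roi_to_mm(trial$roi, cal))
}
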