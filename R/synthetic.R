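# Body templates in mm relative to the centroid, heading along +x.
# Dam nose-spine1 = 20 mm; the P5 pup is a 0.6-scale copy (nose-spine1 =
# 12 mm), roughly the landmark span ratio of a P5 pup to an adult dam.
dam_template_mm <- function() rbind(
  nose = c(30, 0), ear_left = c(20, 8), ear_right = c(20, -8),
  spine1 = c(10, 0), spine2 = c(0, 0), spine3 = c(-12, 0),
  tail_base = c(-25, 0))
pup_template_mm <- function() 0.6 * dam_template_mm()

#' Describe a synthetic PRT trial
#'
#' A scenario scripts one simulated pup retrieval trial: the recording
#' geometry (1280 x 720 px frame, cage-lid calibration landmarks 530 px
#' apart so that the standard 265 mm reference gives 0.5 mm/px), the nest
#' polygon and core-nest circle in one cage corner, the pup drop point in
#' the opposite corner, and an ordered episode script. Episode behaviors:
#'
#' * `idle` — dam wanders in place (small Gaussian steps), pup jitters;
#' * `approach` — dam locomotes straight toward the pup at
#'   `approach_mm_s` until its nose is within `coupling_mm` of the pup
#'   centroid; frames where it actually closes in are labelled approach;
#' * `carry` — dam transports the pup (pup centroid rides within
#'   `coupling_mm` of the dam nose) toward the core nest at `carry_mm_s`;
#'   moving frames are labelled carry; reaching the core nest releases the
#'   pup inside the nest (a retrieval);
#' * `dig` — dam sits at the core nest with oscillatory part motion
#'   (`dig_amplitude_mm`, `dig_freq_hz`); labelled digging;
#' * `return` — dam walks back to the nest without the pup (the common
#'   abortive-approach pattern); locomotion, but none of the three
#'   behaviors, so these frames are hard negatives for the classifiers;
#' * `pup_drift` — the pup slides toward the nest at `drift_mm_s` with no
#'   carry, emulating the "shifted nest" failure mode in which the ROI
#'   admits the pup without a retrieval.
#'
#' Kinematic realism is minimal but sufficient: the generator exists to
#' exercise the pipeline's logic and give the classifiers learnable
#' structure, not to model mouse biomechanics. Defaults (100 mm/s approach,
#' 70 mm/s carry, 15 mm coupling) are brisk but plausible home-cage speeds.
#'
#' @param fps Frames per second (default 10; recordings vary 10-30).
#' @param trial_s Trial length in seconds (default 90).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param episodes Data frame with columns `behavior`, `start_s`, `end_s`.
#' @param frame_px Video frame size `c(width, height)`.
#' @param landmarks_px List of two `c(x, y)` calibration landmark points.
#' @param reference_mm Landmark separation in mm.
#' @param nest_center_px,nest_radius_px Nest polygon center and
#'   circumradius (a hexagon is generated).
#' @param core_radius_px Core-nest circle radius.
#' @param drop_point_px Pup start location.
#' @param dam_start_px Dam start location (in the nest).
#' @param approach_mm_s,carry_mm_s,drift_mm_s Locomotion speeds.
#' @param coupling_mm Maximum dam-nose-to-pup-centroid distance while
#'   carrying.
#' @param dig_amplitude_mm,dig_freq_hz Digging oscillation parameters.
#' @param turn_rate_deg_s Maximum heading change per second; headings turn
#'   smoothly toward their target so template rotation never mimics a
#'   tracking jump.
#' @param idle_step_px,part_jitter_px,pup_jitter_px Gaussian noise scales
#'   for idle wander, body-part placement and pup jitter.
#' @return Object of class `prt_scenario`.
#' @export
prt_scenario <- function(fps = 10, trial_s = 90, seed = 1,
                         episodes = default_episodes(),
                         frame_px = c(1280, 720),
                         landmarks_px = list(c(375, 60), c(905, 60)),
                         reference_mm = 265,
                         nest_center_px = c(1010, 560),
                         nest_radius_px = 90, core_radius_px = 40,
                         drop_point_px = c(180, 130),
                         dam_start_px = c(990, 545),
                         approach_mm_s = 100, carry_mm_s = 70,
                         drift_mm_s = 8, coupling_mm = 15,
                         dig_amplitude_mm = 6, dig_freq_hz = 2,
                         turn_rate_deg_s = 90,
                         idle_step_px = 0.2, part_jitter_px = 0.15,
                         pup_jitter_px = 0.1) {
  stopifnot(fps > 0, trial_s > 0)
  episodes <- as.data.frame(episodes)
  stopifnot(all(c("behavior", "start_s", "end_s") %in% names(episodes)))
  if (any(episodes$end_s <= episodes$start_s))
    stop("episodes must have end_s > start_s")
  if (any(episodes$start_s < 0) || any(episodes$end_s > trial_s))
    stop("episode times must lie within the trial")
  known <- c("idle", "approach", "carry", "dig", "retrieve", "return",
             "pup_drift")
  if (!all(episodes$behavior %in% known))
    stop("unknown episode behavior(s): ",
         paste(setdiff(episodes$behavior, known), collapse = ", "))
  episodes$behavior[episodes$behavior == "retrieve"] <- "carry"
  episodes <- episodes[order(episodes$start_s), , drop = FALSE]
  carry_eps <- episodes[episodes$behavior == "carry", , drop = FALSE]
  for (i in seq_len(nrow(carry_eps))) {
    prior <- episodes$behavior == "approach" &
      episodes$end_s <= carry_eps$start_s[i] + 1e-9
    if (!any(prior))
      warning("carry episode scripted without a prior approach")
  }
  structure(list(
    fps = fps, trial_s = trial_s, seed = seed, episodes = episodes,
    frame_px = frame_px, landmarks_px = landmarks_px,
    reference_mm = reference_mm, nest_center_px = nest_center_px,
    nest_radius_px = nest_radius_px, core_radius_px = core_radius_px,
    drop_point_px = drop_point_px, dam_start_px = dam_start_px,
    approach_mm_s = approach_mm_s, carry_mm_s = carry_mm_s,
    drift_mm_s = drift_mm_s, coupling_mm = coupling_mm,
    dig_amplitude_mm = dig_amplitude_mm, dig_freq_hz = dig_freq_hz,
    turn_rate_deg_s = turn_rate_deg_s,
    idle_step_px = idle_step_px, part_jitter_px = part_jitter_px,
    pup_jitter_px = pup_jitter_px), class = "prt_scenario")
}

#' @rdname prt_scenario
#' @export
default_episodes <- function() data.frame(
  behavior = c("approach", "carry", "dig"),
  start_s = c(8, 14, 26),
  end_s = c(14, 23, 34), stringsAsFactors = FALSE)

#' Randomized scenario scripts
#'
#' Draws a scenario of one of three trial archetypes with randomized
#' latencies and speeds: `"retrieve"` (0-2 abortive approach bouts, a final
#' approach, then a carry long enough to deliver the pup into the nest,
#' followed by digging at the nest), `"no_retrieve"` (approach bouts,
#' sometimes a carry aborted far from the nest, usually digging; the pup
#' never enters the nest) and `"nest_shift"`
#' (the pup starts just outside the nest polygon and drifts into it with no
#' carry — the ROI-only failure mode).
#'
#' @param seed Integer seed (also stored in the scenario).
#' @param type Trial archetype.
#' @param fps Frames per second.
#' @return A [prt_scenario()].
#' @export
random_scenario <- function(seed,
                            type = c("retrieve", "no_retrieve",
                                     "nest_shift"),
                            fps = 10) {
  type <- match.arg(type)
  set.seed(seed)
  va <- stats::runif(1, 80, 110)   # approach speed mm/s
  vc <- stats::runif(1, 55, 72)    # carry speed mm/s
  dist_to_pup_mm <- 455            # dam start -> drop point, default layout
  dist_to_nest_mm <- 467           # drop point -> core nest
  ta <- dist_to_pup_mm / va + 1    # approach window incl. margin
  args <- list(fps = fps, seed = seed, approach_mm_s = va, carry_mm_s = vc)
  # dams commonly make abortive approaches before committing: 0-2 bouts in
  # which the dam closes part of the distance and then returns to the nest
  # without the pup, before the final approach that reaches it
  approach_bouts <- function(latency) {
    n_ab <- sample(0:2, 1)
    t0 <- latency
    eps <- NULL
    for (k in seq_len(n_ab)) {
      tab <- stats::runif(1, 0.3, 0.5) * ta
      eps <- rbind(eps,
                   data.frame(behavior = "approach", start_s = t0,
                              end_s = t0 + tab),
                   data.frame(behavior = "return", start_s = t0 + tab,
                              end_s = t0 + 2 * tab + 1))
      t0 <- t0 + 2 * tab + 1 + stats::runif(1, 1, 3)
    }
    rbind(eps, data.frame(behavior = "approach", start_s = t0,
                          end_s = t0 + ta))
  }
  if (type == "retrieve") {
    tc <- dist_to_nest_mm / vc + 2
    dig <- TRUE  # dams routinely dig at the nest after retrieving
    latency <- stats::runif(1, 3,
                            max(4, 50 - 3 * ta - tc - (if (dig) 12 else 0)))
    eps <- approach_bouts(latency)
    t1 <- eps$end_s[nrow(eps)]
    eps <- rbind(eps, data.frame(behavior = "carry", start_s = t1,
                                 end_s = t1 + tc))
    if (dig) eps <- rbind(eps, data.frame(
      behavior = "dig", start_s = t1 + tc + 2, end_s = t1 + tc + 10))
  } else if (type == "no_retrieve") {
    carry <- stats::runif(1) < 0.5
    dig <- stats::runif(1) < 0.7
    tc <- if (carry) 0.3 * dist_to_nest_mm / vc else 0
    latency <- stats::runif(1, 3, max(4, 55 - 3 * ta - tc))
    eps <- approach_bouts(latency)
    t1 <- eps$end_s[nrow(eps)]
    if (carry) eps <- rbind(eps, data.frame(
      behavior = "carry", start_s = t1, end_s = t1 + tc))
    if (dig) {
      ds <- t1 + tc + 3
      eps <- rbind(eps, data.frame(behavior = "dig", start_s = ds,
                                   end_s = min(ds + 8, 89)))
    }
  } else {  # nest_shift
    latency <- stats::runif(1, 5, 30)
    eps <- data.frame(behavior = "pup_drift", start_s = latency,
                      end_s = min(latency + 40, 89))
    # pup parked just outside the nest polygon edge
    center <- c(1010, 560)
    u <- c(-0.80, -0.60)
    args$drop_point_px <- center + (90 + 80) * u
  }
  do.call(prt_scenario, c(args, list(episodes = eps)))
}

#' Generate one synthetic PRT trial
#'
#' Simulates the scenario frame by frame and returns the pose track, the
#' frame-accurate ground truth, the ROI configuration and the trial
#' metadata — in exactly the shapes the rest of the pipeline consumes.
#'
#' Ground-truth retrieval is kinematic and independent of the scoring rule:
#' a trial is truly retrieved when a carry delivers the pup into the core
#' nest, and the true retrieval frame is the first frame at which any pup
#' body part lies inside the nest polygon during that carry. A
#' `pup_drift` trial is truly *not* retrieved even though the pup ends up
#' inside the ROI.
#'
#' @param scenario A [prt_scenario()].
#' @return List with elements `track` ([pose_track()], px), `truth`
#'   (per-frame 0/1 `labels` matrix for approach/carry/digging,
#'   `retrieved`, `retrieval_frame` 0-based or `NA`, `retrieval_time_s`),
#'   `roi` ([roi_config()], px), and `meta` ([trial_meta()]).
#' @export
generate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "prt_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  scale <- sc$reference_mm /
    sqrt(sum((sc$landmarks_px[[1]] - sc$landmarks_px[[2]])^2))  # mm per px
  mm2px <- function(mm) mm / scale
  nf <- as.integer(round(sc$trial_s * sc$fps))
  dt <- 1 / sc$fps

  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  nest_poly <- cbind(sc$nest_center_px[1] + sc$nest_radius_px * cos(ang),
                     sc$nest_center_px[2] + sc$nest_radius_px * sin(ang))
  roi <- roi_config(nest_poly, sc$nest_center_px, sc$core_radius_px,
                    trial_id = sprintf("synthetic_%d", sc$seed))

  dam_t <- mm2px(dam_template_mm())
  pup_t <- mm2px(pup_template_mm())
  np <- nrow(dam_t)
  coupling_px <- mm2px(sc$coupling_mm)
  arrive_px <- dam_t["nose", 1] + coupling_px  # centroid gap when attached
  osc_dir <- matrix(stats::rnorm(np * 2), np, 2)
  osc_dir <- osc_dir / sqrt(rowSums(osc_dir^2))
  osc_phase <- stats::runif(np, 0, 2 * pi)

  dam_c <- sc$dam_start_px
  pup_c <- sc$drop_point_px
  dam_h <- c(-1, 0); pup_h <- c(1, 0)  # headings (unit vectors)
  max_turn <- sc$turn_rate_deg_s * pi / 180 * dt  # rad per frame
  attached <- FALSE; delivered <- FALSE
  carry_active <- logical(nf)

  x <- matrix(0, nf, 2L * np); y <- matrix(0, nf, 2L * np)
  labels <- matrix(0L, nf, 3L,
                   dimnames = list(NULL, c("approach", "carry", "digging")))

  ep_at <- function(time) {
    hit <- which(sc$episodes$start_s <= time & time < sc$episodes$end_s)
    if (length(hit) == 0L) "idle" else sc$episodes$behavior[hit[1L]]
  }
  clamp <- function(p) pmin(pmax(p, c(5, 5)), sc$frame_px - 5)
  step_toward <- function(from, to, step) {
    d <- sqrt(sum((to - from)^2))
    if (d <= step) list(pos = to, moved = d, dir = (to - from) / max(d, 1e-9))
    else list(pos = from + step * (to - from) / d, moved = step,
              dir = (to - from) / d)
  }
  # rotate heading h toward target direction by at most `rate` radians
  turn_toward <- function(h, target, rate = max_turn) {
    a <- atan2(h[2], h[1])
    b <- atan2(target[2], target[1])
    d <- (b - a + pi) %% (2 * pi) - pi
    a <- a + sign(d) * min(abs(d), rate)
    c(cos(a), sin(a))
  }

  for (t in seq_len(nf)) {
    time <- (t - 1L) * dt
    ep <- ep_at(time)
    dig_now <- FALSE

    if (ep == "approach" && !attached) {
      gap <- sqrt(sum((pup_c - dam_c)^2))
      if (gap > arrive_px) {
        s <- step_toward(dam_c, pup_c, mm2px(sc$approach_mm_s) * dt)
        if (sqrt(sum((s$pos - pup_c)^2)) < arrive_px)
          s$pos <- pup_c - arrive_px * s$dir
        dam_c <- s$pos; dam_h <- turn_toward(dam_h, s$dir)
        labels[t, "approach"] <- 1L
      } else {
        dam_c <- clamp(dam_c + stats::rnorm(2, 0, sc$idle_step_px))
      }
    } else if (ep == "carry" && !delivered) {
      gap <- sqrt(sum((pup_c - dam_c)^2))
      if (!attached && gap > arrive_px * 1.05) {
        s <- step_toward(dam_c, pup_c, mm2px(sc$carry_mm_s) * dt)  # transit
        dam_c <- s$pos; dam_h <- turn_toward(dam_h, s$dir)
      } else {
        # the dam grips the pup and pivots about her mouth: the nose
        # advances toward the nest while the body hangs from it
        attached <- TRUE
        nose_old <- dam_c + dam_t["nose", 1] * dam_h
        s <- step_toward(nose_old, sc$nest_center_px,
                         mm2px(sc$carry_mm_s) * dt)
        if (s$moved > 1e-6) dam_h <- turn_toward(dam_h, s$dir)
        dam_c <- s$pos - dam_t["nose", 1] * dam_h
        labels[t, "carry"] <- 1L
        carry_active[t] <- TRUE
      }
    } else if (ep == "return") {
      anchor <- sc$nest_center_px
      if (sqrt(sum((anchor - dam_c)^2)) > 30) {
        s <- step_toward(dam_c, anchor, mm2px(sc$approach_mm_s) * dt)
        dam_c <- s$pos; dam_h <- turn_toward(dam_h, s$dir)
      } else {
        dam_c <- clamp(dam_c + stats::rnorm(2, 0, sc$idle_step_px))
      }
    } else if (ep == "dig") {
      anchor <- sc$nest_center_px
      if (sqrt(sum((anchor - dam_c)^2)) > 10) {
        s <- step_toward(dam_c, anchor, mm2px(sc$approach_mm_s) * dt)
        dam_c <- s$pos; dam_h <- turn_toward(dam_h, s$dir)
      } else {
        dig_now <- TRUE
        labels[t, "digging"] <- 1L
        dam_c <- clamp(dam_c + stats::rnorm(2, 0, sc$idle_step_px))
      }
    } else {
      dam_c <- clamp(dam_c + stats::rnorm(2, 0, sc$idle_step_px))
    }

    # pup kinematics: carried pups track the dam's mouth with a smoothed,
    # coupling-clamped path so turning never mimics a tracking jump
    if (attached && !delivered && carry_active[t]) {
      nose <- dam_c + dam_t["nose", 1] * dam_h
      target <- nose + 0.2 * coupling_px * dam_h
      pup_c <- pup_c + 0.5 * (target - pup_c)
      gap <- sqrt(sum((pup_c - nose)^2))
      if (gap > 0.95 * coupling_px)
        pup_c <- nose + 0.95 * coupling_px * (pup_c - nose) / gap
      # a gripped pup is dragged and reorients slowly
      pup_h <- turn_toward(pup_h, dam_h, rate = max_turn / 2)
      if (sqrt(sum((pup_c - sc$nest_center_px)^2)) <
          0.8 * sc$core_radius_px) {
        attached <- FALSE; delivered <- TRUE  # pup released in core nest
      }
    } else if (ep == "pup_drift") {
      s <- step_toward(pup_c, sc$nest_center_px, mm2px(sc$drift_mm_s) * dt)
      pup_c <- s$pos; pup_h <- turn_toward(pup_h, s$dir)
    } else {
      pup_c <- clamp(pup_c + stats::rnorm(2, 0, sc$pup_jitter_px))
    }

    rot <- function(h) matrix(c(h[1], h[2], -h[2], h[1]), 2, 2)
    dam_pts <- sweep(dam_t %*% t(rot(dam_h)), 2, dam_c, "+") +
      matrix(stats::rnorm(np * 2, 0, sc$part_jitter_px), np, 2)
    if (dig_now)
      dam_pts <- dam_pts + mm2px(sc$dig_amplitude_mm) *
        sin(2 * pi * sc$dig_freq_hz * time + osc_phase) * osc_dir
    pup_pts <- sweep(pup_t %*% t(rot(pup_h)), 2, pup_c, "+") +
      matrix(stats::rnorm(np * 2, 0, sc$part_jitter_px), np, 2)

    x[t, ] <- c(dam_pts[, 1], pup_pts[, 1])
    y[t, ] <- c(dam_pts[, 2], pup_pts[, 2])
  }

  parts <- data.frame(
    label = paste(rep(PRT_ANIMALS, each = np), rownames(dam_t), sep = "_"),
    animal = rep(PRT_ANIMALS, each = np),
    part = rep(rownames(dam_t), 2L), stringsAsFactors = FALSE)
  lik <- matrix(stats::runif(nf * 2L * np, 0.9, 1), nf, 2L * np)
  track <- pose_track(x, y, lik, parts, fps = sc$fps, unit = "px")

  occ <- roi_occupancy(track, roi, "pup", "nest", "any")
  retrieval_frame <- NA_integer_
  if (delivered) {
    first_in <- which(occ & carry_active)[1L]
    if (!is.na(first_in)) retrieval_frame <- first_in - 1L  # 0-based
  }
  truth <- list(
    labels = labels,
    retrieved = as.integer(delivered && !is.na(retrieval_frame)),
    retrieval_frame = retrieval_frame,
    retrieval_time_s = if (is.na(retrieval_frame)) sc$trial_s
                       else retrieval_frame / sc$fps)

  meta <- trial_meta(trial_id = roi$trial_id, fps = sc$fps,
                     max_trial_s = sc$trial_s,
                     calibration_reference_mm = sc$reference_mm,
                     calibration_px = sc$landmarks_px)
  list(track = track, truth = truth, roi = roi, meta = meta,
       scenario = sc)
}

#' Inject synthetic tracking errors
#'
#' Emulates the tracking failures the quality control targets: each
#' part-frame is independently teleported with probability `jump_rate` by
#' `jump_magnitude_factor` times that animal's movement criterion in a
#' uniformly random direction, for a single frame; occluded part-frames get
#' their likelihood redrawn below 0.2. The registry records every injected
#' jump with the part's true location, so correction accuracy is
#' measurable.
#'
#' @param track A clean [pose_track()].
#' @param jump_rate Per part-frame teleport probability in \[0, 1\].
#' @param jump_magnitude_factor Jump size as a multiple of the animal's
#'   movement criterion (from [compute_criteria()] at default factors).
#' @param occlusion_rate Per part-frame probability of a likelihood drop.
#' @param seed Integer seed.
#' @return List with `track` (noisy copy) and `registry` (data frame:
#'   0-based `frame`, `part`, `true_x`, `true_y`).
#' @export
inject_tracking_noise <- function(track, jump_rate,
                                  jump_magnitude_factor = 3,
                                  occlusion_rate = 0, seed = 1) {
  stopifnot(inherits(track, "pose_track"))
  if (jump_rate < 0 || jump_rate > 1 || occlusion_rate < 0 ||
      occlusion_rate > 1)
    stop("rates must lie in [0, 1]")
  set.seed(seed)
  nf <- n_frames(track); np <- nrow(track$parts)
  crit <- compute_criteria(track)
  mv <- vapply(track$parts$animal,
               function(a) crit$animals[[a]]$movement, 0)
  hit <- matrix(stats::runif(nf * np) < jump_rate, nf, np)
  reg <- NULL
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    theta <- stats::runif(nrow(idx), 0, 2 * pi)
    mag <- jump_magnitude_factor * mv[idx[, 2]]
    reg <- data.frame(frame = idx[, 1] - 1L,
                      part = track$parts$label[idx[, 2]],
                      true_x = track$x[hit], true_y = track$y[hit])
    track$x[hit] <- track$x[hit] + mag * cos(theta)
    track$y[hit] <- track$y[hit] + mag * sin(theta)
  } else {
    reg <- data.frame(frame = integer(0), part = character(0),
                      true_x = numeric(0), true_y = numeric(0))
  }
  if (occlusion_rate > 0) {
    occ <- matrix(stats::runif(nf * np) < occlusion_rate, nf, np)
    track$likelihood[occ] <- stats::runif(sum(occ), 0, 0.2)
  }
  list(track = track, registry = reg)
}
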