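---
title: "Automated scoring of the pup retrieval test: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoring of the pup retrieval test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prtkit)
```

## The assay and the pipeline

In the pup retrieval test (PRT), a pup is taken from the nest and placed in
the most distant corner of the home cage while the dam is in the nest; the
trial ends when the dam carries the pup back to the nest, or after a
maximum trial time (90 s in the standard protocol, the value assigned to
unretrieved trials). Manual scoring of latency and retrieval success is
slow and rater-dependent. prtkit implements an automated alternative that
starts from pose-estimation output — per-frame (x, y, likelihood)
coordinates for 7 dam and 7 pup body parts (nose, both ears, three spine
points, tail base) — and ends with per-trial retrieval status, retrieval
time, and latency/duration/count for three maternal behaviors: approach,
carrying, and digging.

The stages, each exposed as ordinary functions:

1. **Quality control** (`compute_criteria()`, `correct_outliers()`).
2. **Distance standardization** (`calibrate()`, `to_mm()`).
3. **ROI occupancy** (`roi_config()`, `roi_occupancy()`).
4. **Feature extraction** (`extract_features()`).
5. **Frame classification** (`train_forest()`, `select_threshold()`,
   `predict_frames()`, `enforce_min_bout()`).
6. **Retrieval scoring** (`score_retrieval()`, `behavior_summary()`,
   `score_trial()`).
7. **Evaluation statistics** (`confusion_counts()`,
   `classification_report()`, `clopper_pearson()`,
   `pearson_correlation()`).
8. **Synthetic data** (`prt_scenario()`, `generate_trial()`,
   `inject_tracking_noise()`) and **batch orchestration**
   (`run_trial_analysis()`).

## Tracking quality control

Pose estimators occasionally emit impossible locations or movements.
Both are detected against criteria scaled to the animal's own size: the
median of the frame-wise nose-to-spine1 distance, computed per animal (a
P5 pup spans well under the dam's landmark distances, so a shared
criterion would over-correct the dam or under-correct the pup). The movement criterion is
that median times 2.5; the location criterion is the median times 4. Both
factors are arguments with those defaults.

The correction rule is carry-forward: a part whose displacement from its
*last accepted* location exceeds the movement criterion is replaced by that
location (frame 0 is always accepted); then, on a snapshot of the
movement-corrected coordinates, a part lying farther than the location
criterion from at least two other parts of the same animal is replaced by
its last non-outlying location. Carry-forward preserves causality (no
look-ahead) and makes the pass idempotent on isolated errors. Its
restoration accuracy is bounded by the animal's true inter-frame
displacement: a jump landing on a frame where the animal is quasi-
stationary is restored to sub-pixel accuracy, while one landing mid-dash
can only be restored to within one frame's travel (~2 mm at 100 mm/s and
30 fps, more at lower frame rates). For the same reason a *sustained*
super-criterion motion would lock the carried-forward value until the
part returns; real locomotion at 10–30 fps stays far below the criterion,
and the synthetic generator therefore bounds its turning rate so that
template rotation never mimics a jump. Pathological whole-animal
teleports may need repeated passes; one pass handles isolated errors,
which is what tracking glitches look like in practice.

Likelihoods are carried through untouched — the quality control is purely
distance-based. An optional carry-forward likelihood floor
(`apply_likelihood_floor()`, default off) is available for recordings with
heavy occlusion.

## Distance standardization and ROIs

Pixel coordinates are standardized to millimeters with a single landmark:
the distance between the top lids of the home cage, 265 mm in the standard
recording geometry (one figure in the original protocol annotates the
same landmark as 267 mm; the Results value of 265 mm is the default and
the parameter is configurable). `to_mm()` refuses to scale a track twice.

Two fixed regions of interest are defined per video: the *nest*, a simple
polygon around the entire nesting site, and the *core nest*, a circle
around the spot where the pups lie. Boundary points count as inside for
both shapes — ROI edges matter for retrieval scoring, and an inclusive,
documented convention is reproducible. ROIs are fixed for the whole trial;
a nest that shifts mid-trial is a known failure mode (the generator's
`pup_drift` scenario emulates its signature), not something the pipeline
models.

## Features

The original protocol delegates feature construction to its classification
tool and never enumerates the set, so prtkit defines its own minimal,
versioned registry (returned as an attribute of `extract_features()` and
persisted by `write_features()`): dam-nose-to-pup distance,
centroid-to-centroid distance, its signed derivative and the
speed-invariant closing-rate ratio (derivative over mean dam movement),
distances of both
centroids to the nest centroid and core-nest center, per-part
displacements and per-animal means, within-animal body spread, and 0/1 ROI
flags, each augmented with centered rolling mean/median/sd over 0.2, 0.5
and 1.0 s windows (seconds are converted to frames and rounded, minimum
one frame, so 10 and 30 fps recordings are comparable; edges are padded by
replication). Classifiers trained here are therefore *not*
weight-compatible with models trained in other toolchains — compatibility
is at the level of the procedure, which is the reproducible part.
ROI-relative features are included for all three behaviors; digging is the
behavior most driven by them, and a classifier meant to transfer across
cage layouts can simply drop those columns before training.

## Classifiers

One probability random forest per behavior, with the protocol's
hyperparameters: 2000 trees, sqrt feature subsampling, minimum node size 1.
The forests are fitted with ranger; the original protocol's entropy split
criterion is not offered by the R forest implementations, so Gini impurity
is used — the two criteria choose near-identical splits in practice, and
every other hyperparameter matches. Training seeds are mandatory arguments
and are recorded in the bundle, making training bit-reproducible.

Annotated frames are split 75:25 (stratified, seeded) into train and test;
behavior-present frames are rare, so the absent class of the *training*
split is randomly undersampled at a per-behavior ratio. The discrimination
threshold is chosen on the untouched 25 % split as the value maximizing
the present-class f1 over the union of the unique held-out probabilities
and a 0.01 grid; since f1 is piecewise constant between observed
probabilities, this candidate set contains a global maximizer. Ties break
toward the lowest threshold (favoring sensitivity); a frame counts as
present when its probability is greater than or *equal to* the threshold.
Both conventions are documented because the original protocol states
neither.

Predictions are smoothed *after* thresholding by removing bouts shorter
than a per-behavior minimum duration; smoothing never creates
present-frames and is idempotent. The per-behavior settings fitted during
the original protocol's development ship as `classifier_presets()` —
undersample ratios 8.5/16/2, thresholds 0.47/0.47/0.24, minimum bouts
500/200/1000 ms for approach/carry/digging. They are dataset-specific
presets, not universal constants; new datasets should refit the threshold.

## The retrieval rule

A trial is scored retrieved when at least one pup body part enters the
nest ROI *and* carry was observed in the three seconds before entering.
The look-back window is left-closed, right-open, `round(3 fps)` frames
long, clipped at frame 0. Design choices the rule's wording leaves open,
resolved here and tested:

* "Entering" is the false-to-true transition of pup nest occupancy; a
  trial starting with the pup already inside counts as an entry at frame 0
  with an empty window, which cannot qualify (conservative).
* The window is strictly before the entry frame; carry on the entry frame
  itself does not count.
* Every entry event is examined in order, not just the first — a pup that
  briefly clips the ROI boundary early (a "boundary error" in manual
  terms) does not spoil a later genuine retrieval.
* Carry labels fed to the rule are post-smoothing.

Retrieval time is the qualifying entry frame divided by fps; unretrieved
trials are assigned the maximum trial time, exactly as in manual scoring.
Latency, total duration and bout count per behavior come from
`behavior_summary()` with the same never-occurred convention.

## Evaluation statistics

`classification_report()` reproduces the original validation arithmetic:
accuracy with its exact (Clopper–Pearson) binomial interval, and
sensitivity/specificity under an explicit positive-class convention. The
default `positive_label = 0` treats the *absent / not retrieved* level as
positive — the first-factor-level convention of the evaluation package
used in the original analysis, and the only reading consistent with its
published rates (e.g. retrieval sensitivity 16/22 = 72.7 %). The
convention is stored in the report so it cannot be misread. The published
frame-level and trial-level confusion matrices ship as
`benchmark_matrices()`; reproducing their rates is part of the test suite.
One internal inconsistency is worth knowing about: the published digging
matrix yields a sensitivity of 81.75 %, which its accompanying text
rounds to 81.8 % while the matrix arithmetic prints 81.7 %; the matrices
are treated as authoritative.

## The synthetic generator

`generate_trial()` simulates a dam and pup in the standard recording
geometry: a 1280 × 720 px frame, cage-lid landmarks 530 px apart (so the
265 mm reference gives 0.5 mm/px), a hexagonal nest in one corner with a
core-nest circle, the pup dropped in the opposite corner, 90 s at 10 fps
by default. Trials are scripted as episodes (idle, approach, carry, dig,
pup drift); the kinematic state machine labels frames by what actually
happens, so labels are frame-accurate by construction. Default kinematics
are chosen once for plausibility: approach at 100 mm/s, carry at 70 mm/s
(brisk but ordinary home-cage locomotion), a 15 mm mouth-to-pup coupling
distance, heading turn rate capped at 90°/s (with carrying dams pivoting about
the mouth, so the gripped pup does not sweep an arc), dam nose-to-spine1
20 mm with a 0.6-scale P5 pup, digging as 6 mm / 2 Hz part oscillation, and
sub-pixel idle jitter. `random_scenario()` draws three trial archetypes —
retrieval, non-retrieval, and a nest-shift-like drift in which the pup
enters the ROI without carry — with randomized latencies and speeds.

Ground-truth retrieval is kinematic (a carry that delivers the pup into
the nest; the true retrieval frame is the first pup-part-in-nest frame),
deliberately *not* defined by running the scoring rule, so the test that
the rule recovers the truth is a genuine check of the window arithmetic.
`inject_tracking_noise()` adds the failure modes the quality control
targets — single-frame teleports of configurable magnitude (in multiples
of the movement criterion) and likelihood drops below 0.2 — and registers
every injection so correction accuracy is measurable.

What the generator does *not* emulate: video appearance, pose-estimator
error structure (correlated drift, identity swaps), multi-pup litters,
nest deformation, or realistic mouse gait. Tests passing on synthetic
trials show the *logic* of the pipeline is right (the scoring rule, the
correction rule, the threshold search, the bout arithmetic) and that the
classifiers can learn clean structure; they do not certify performance on
real videos, which is what the shipped benchmark matrices describe.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: zero-median tracks, already-millimeter
tracks, coincident calibration landmarks, self-intersecting nest polygons,
single-class training data, thresholds with no positive labels. Rates with
an empty denominator class are `NA`, not errors. All rates are stored at
full precision and rounded only for printing.

The test suite and the acceptance script exercise the pipeline at sizes a
laptop handles comfortably: 900-frame (90 s × 10 fps) trials, batches of
6–15 trials for training and scoring, 200 trials for the retrieval-rule
property, 10^4 random point/polygon pairs for the geometry oracle, and
2000-tree forests on ~10 annotated synthetic trials. These sizes were
chosen as the smallest at which every property is measured with
comfortable statistical margin.

## Known limitations

* Classifier presets (thresholds, ratios, bout lengths) are fitted to one
  dataset; transfer to other labs requires refitting.
* Carry-forward restoration accuracy degrades with locomotion speed and
  falling frame rate, as quantified above.
* Fixed ROIs cannot represent a nest that shifts mid-trial; the rule's
  carry requirement guards against scoring such trials as retrieved, but
  a shifted nest can still cost a true retrieval.
* The retrieval rule inherits the resolution of the carry classifier: a
  missed carry bout within the window turns a true retrieval into a miss.
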