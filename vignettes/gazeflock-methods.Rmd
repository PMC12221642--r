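---
title: "From head markers to collective gaze statistics: the gazeflock methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From head markers to collective gaze statistics: the gazeflock methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazeflock quantifies gaze following in a flock of birds tracked by
marker-based motion capture. A stimulus structure between two tables
presents a moving object through a window visible from one side only;
birds on that side (demonstrators) can provide gaze cues, birds on the
other side (observers) cannot see the object and may follow those cues.
The pipeline turns raw head-marker trajectories into per-frame head
poses, reprojects visual-field cones, segments filtered looking bouts,
assembles a per-observer, per-presentation response table, and fits
binomial and Poisson mixed models of the condition effect and of the
effect of the number of demonstrators. This vignette describes the
model at each stage, the tunable parameters, the synthetic-data
generator used for validation, and the limitations of both.

```{r setup}
library(gazeflock)
```

## The head-local coordinate system

Each bird carries four head markers whose positions relative to the
eyes and beak tip are known from a one-off calibration (`head_calibration`).
Per frame, the calibration template is aligned onto the observed
markers by a least-squares rigid transform (`rigid_align`, the Kabsch
construction with an explicit proper-rotation constraint: reflections
are never returned). Frames with fewer than three valid markers are
marked invalid rather than guessed.

The head frame (`build_head_frame`) follows the field's convention for
this rig class: the origin is the midpoint of the two eyes, and the
forward (+Y) axis points to the horizon, defined as 30 degrees above
the origin-to-beak line in elevation. The rotation that raises the beak
line happens in the plane spanned by the beak direction and the head-up
direction; head-up is recorded in the calibration (defaulting to the
eye-axis/beak normal pointing dorsally) so the construction does not
depend on the capture rig's orientation. The remaining axes are fixed
by convention: +X toward the right eye (orthogonalized against Y) and
Z = X x Y, giving a right-handed frame in which negative azimuth is the
bird's left. In the resulting frame the beak sits at exactly -30
degrees elevation and azimuth 0 — a property the test suite asserts to
machine precision on reconstructed data.

Pose series are then smoothed (`smooth_poses`): gaps up to
`max_gap_frames` (default 10) are filled — positions linearly,
rotations by geodesic interpolation — and a zero-phase moving average
(window `window_frames`, default 3) is applied to positions and to
orientations in the rotation-vector domain, with re-orthonormalization.
The 3-frame window was chosen once as the widest smoother that smears
an instantaneous head saccade across at most one frame on each side;
this keeps bout onsets within the two-frame timing guarantee the
synthetic generator promises (below). A wider window suppresses more
jitter but trades it directly for timing bias at saccade boundaries.

## Gaze cones and regions of interest

Pigeons fixate distant objects with laterally projecting foveae and use
the frontal binocular overlap (about 20 degrees wide) for close or
slowly moving targets. Three cones model this (`default_cone_specs`):
center lines at +/-75 degrees azimuth, 0 elevation (left/right fovea)
and at 0/0 (binocular), each with a 10-degree half angle that absorbs
eye movement and residual noise. For the binocular cone the 10-degree
half angle reproduces the ~20-degree field width. The lower-frontal
field gets no cone: it is used for ground objects at pecking distance,
not for the elevated stimulus windows. All of this is configuration,
not code (`scene_config`).

A region of interest is a sphere of 0.25 m radius around a stimulus
window center, covering the 30 cm window plus a 10 cm margin on each
side. The two side windows of one tube location are a fraction of the
sphere radius apart, so the package models one sphere per location
(top/bottom); which table can see the object is a property of the
schedule (`demonstrator_side`), not of the geometry. A cone crosses a
sphere when the apex is inside it, or when the angle between the cone
axis and the apex-to-center direction is at most the half angle plus
the sphere's angular radius `asin(r/d)` — an exact closed form that the
tests verify against a brute-force ray-sampling oracle.

## From crossings to "looks"

A frame counts toward a look at an ROI when (a) at least one cone
crosses the sphere, (b) the pose is valid, (c) the frame is not part of
a head saccade, and (d) the bird is not grooming. Saccades are frames
whose geodesic angular speed to the previous valid frame exceeds
`saccade_threshold_deg_s` (default 300 deg/s; avian visual processing
is suppressed during rapid head rotation, and head bobbing stays far
below this threshold). Grooming is detected by a reference heuristic —
head pitch below -45 degrees with the eye midpoint within 0.15 m of the
backpack centroid, sustained for at least 400 ms — or supplied as an
external mask from a dedicated classifier, passed through verbatim.
Both detectors are stand-ins for rig-specific tooling and all their
thresholds live in `scene_config`.

Maximal runs of hit frames lasting at least `fixation_min_ms` (default
300 ms) become bouts (`detect_looks`). Flagged frames break runs; no
gap bridging is applied, because the exclusion of saccade and grooming
frames is a frame-level statement. Cones are OR-ed *before*
segmentation, so a simultaneous fovea + binocular crossing is one look,
not two; each bout is labeled with the cone holding the majority of its
hit frames, ties resolved in favor of a fovea. One could instead count
per-cone bouts separately; the OR-then-segment rule was chosen to avoid
double-counting a single orienting event, and is the documented unit of
the count response.

## The observer table and exclusions

For each presentation, birds are assigned to a table side by the region
containing their median backpack position (`assign_sides`); birds seen
in both regions are flagged `switched`, birds seen outside both are
flagged `flew_off`, fully missing birds `untracked`. One row per
observer-side bird per presentation records the binary and count
responses at the target and distractor locations, the first-looked
location (identical onsets at both — possible with two foveae — are
recorded as `none`), the number of demonstrator-side birds, and the
"actual number of demonstrators": demonstrator-side birds with at least
one target bout during the presentation, where a demonstrator look
counts for a given observer only if it overlaps at least one frame in
which that observer was not grooming. The any-overlap rule (rather than
requiring the whole look outside observer grooming) is the package's
documented choice; it is monotone — removing observer grooming never
lowers the count — and the tests assert that property.

Exclusions (`apply_exclusions`) drop rows of observers that switched,
flew off or were untracked, and all rows of *test* presentations in
which no demonstrator looked at the target. The no-demonstrator rule is
evaluated on demonstrator bouts before any observer-grooming filtering,
because it is a property of the presentation, not of an observer; it
never applies to control presentations.

## The mixed models

The observation unit is one observer in one presentation. Binary
responses (likelihood of looking, first look at target) are modeled
with binomial GLMMs, counts (number of looks) with Poisson GLMMs
(`fit_glmm`, via lme4's Laplace approximation). The main predictor is
either condition (coded control = 0, test = 1, so positive estimates
mean more looking under demonstration) or the z-scored number of
(actual) demonstrators; control predictors are trial number,
presentation number, presentation location and, for combined analyses,
experiment id. All numeric predictors are z-scored with the n-1 sd
convention on the modeled rows, so combined and per-experiment analyses
scale independently. Random structure follows the maximal design:
per-individual intercepts plus slopes for all fixed effects with
estimated correlations. Non-convergence triggers a documented fallback
ladder — drop the correlations, then the slopes — and the ladder step
actually used is recorded in the result, so any deviation from the
maximal structure is explicit.

Each tested predictor gets a chi-square(1) likelihood-ratio test
against the model without that fixed effect, holding the random
structure fixed (retaining the random slope in the reduced model, the
conservative convention for such designs); Wald chi-squares are
available as an alternative (`wald_tests`). Model classes — linear vs
quadratic demonstrator effect, actual vs configured demonstrators — are
compared by AIC (`compare_models`). Confidence bands for predictions
are simulation-based (`simulate_ci`): 10,000 draws of the fixed effects
from their asymptotic multivariate normal distribution, pushed through
the inverse link with all other variables held at their means, and
summarized by the 2.5th and 97.5th percentiles. Diagnostics
(`glmm_diagnostics`) report the Pearson overdispersion ratio (for the
Poisson assumption), variance-inflation factors from the fixed-effects
design, and a leave-one-individual-out Cook's distance on the fixed
effects, which identifies individuals that drag the estimates. No
multiple-testing correction is applied: each question is answered by a
single pre-specified test, and this is stated rather than adjusted.

## The synthetic generator

Every stage is validated against data with known ground truth, because
no deposited dataset ships with the package.

`generate_flock_trajectories` emits marker-level scenarios: rigid
4-marker heads on two tables, piecewise-constant head fixations
separated by instantaneous orientation jumps (the avian head-saccade
pattern, which makes the saccade filter testable by construction),
scripted look events during which the designated cone's center line
points exactly at the ROI center, wandering fixations that keep every
cone at least 5 degrees clear of every sphere, grooming bouts with a
stereotyped 60-degree head-down posture next to the backpack, and
scripted table switches and fly-offs for the exclusion logic. Markers
are corrupted with isotropic Gaussian noise (default sd 0.3 mm, the
precision class of a calibrated infrared rig — on a 2 cm marker
cluster this leaves orientation jitter comfortably below the saccade
threshold) and per-marker dropout (default 2%). All randomness flows
from one seed with deterministic per-bird substreams. Events shorter
than the fixation threshold are emitted but marked sub-threshold: the
pipeline must *not* recover them, and the tests check that too.

`generate_response_table` is the statistical twin of the observer
table: binary and count responses drawn from
`eta = baseline + beta_cond * cond + beta_dem * z + beta_dem2 * z^2 +
b0_i + bc_i * cond + bd_i * z` with independent Gaussian per-individual
effects, z the z-scored demonstrator count. Its defaults mirror the
effect sizes at the combined-data scale (`beta_dem = 0.324`,
`beta_cond = 0.425`, 70 individuals, about 1,500 rows) with moderate
random-effect spread (intercept sd 0.5, slope sds 0.2) — values chosen
once as a realistic regime for per-presentation look counts of order
one. The two responses are independent draws from the same linear
predictor; the twin feeds the model stage one response at a time and
does not claim the joint structure of a real bout table.

What the generator does *not* emulate: locomotion and feeding, body
posture beyond a rigid head at a table position, marker identity swaps
between birds (the upstream relabeling problem is out of scope —
dropout and gaps stand in for imperfect tracking), occlusion, and any
dependence of looking on what other birds are doing at the same
moment beyond the scheduled event structure. Passing the recovery tests
therefore demonstrates the correctness of the geometry, segmentation,
bookkeeping and inference — not robustness to identity errors or to
behaviors the generator never produces.

## Numerical choices and degenerate inputs

* Rotations are smoothed in the rotation-vector domain with
  branch-continuity correction; results are re-orthonormalized through
  an SVD projection.
* `rigid_align` requires three valid markers; two or fewer yield an
  invalid frame, never an exception. Degenerate calibrations (beak on
  the eye axis, rank-deficient template) are rejected at construction.
* Cone/sphere borderline cases: the closed form is exact; the test
  oracle excludes configurations within 0.1 degrees of the boundary,
  where ray sampling itself is unreliable.
* A constant response (e.g. all zeros) is returned as a flagged,
  non-converged `glmm_result` rather than an error, so batch harnesses
  survive degenerate cells.
* Likelihood-ratio statistics are floored at zero (optimizer noise can
  produce tiny negative differences).
* Bout timing: the 3-frame smoother plus the flagged transition frame
  shift recovered onsets by exactly two frames relative to the
  scripted jump; this systematic offset is the documented timing
  resolution of the pipeline.

## Problem sizes used in the shipped validation

The shipped tests and the acceptance script size their simulations as
follows: geometry oracle on 1,000 random cone/sphere configurations at
10,000 rays each; bout recovery on a 10-bird flock with 40 scheduled
supra-threshold events across four 8 s presentations at 100 Hz;
coverage of the demonstrator effect over 200 replicates at the
combined-data scale (1,470 rows, 70 individuals); type-I calibration
over 1,000 replicates at a moderate scale (320 rows, 40 individuals,
random-intercept models in both truth and fit, for speed); and
linear-vs-quadratic AIC selection over 200 replicates. The capture
frame rate is rig-dependent and therefore required configuration; 100
Hz is the package default and the rate used throughout the validation.

## Known limitations

* Head orientation is the gaze proxy; eye-in-head movement is absorbed
  by the 10-degree cone margin, not modeled.
* The saccade and grooming detectors are reference stand-ins for
  rig-specific tooling; their thresholds are configuration, and an
  external grooming mask can replace the heuristic entirely.
* When a marker-dropout gap coincides with a scripted event onset, gap
  interpolation adds one flagged frame and the recovered onset can
  shift by three frames instead of the systematic two.
* Identity maintenance across birds is assumed correct upstream.
* The quadratic term tests for curvature of the demonstrator-count
  effect; fitting an explicit quorum-response model is out of scope.
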