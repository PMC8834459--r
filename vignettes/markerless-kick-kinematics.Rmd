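---
title: "Markerless kick kinematics: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless kick kinematics: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinekick)
```

This vignette is the package's own account of the science it implements:
the models behind each pipeline stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design decisions taken where more than
one defensible choice existed. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The measurement problem

A soccer kick is recorded by several synchronised cameras around the pitch.
A markerless pose estimator reduces each video frame to 25 image-plane
keypoints per detected person, each with a confidence score. The package
turns those per-frame detections into 3D kick kinematics — marker
trajectories, velocities, joint angles — and provides the statistics used
to judge whether the markerless signal agrees with a reference method
(manual digitisation) well enough to replace it.

## Pose-track association

Pose estimators emit unordered per-frame detections; identity over time
must be reconstructed. Each pose is summarised by its **centre of mass**:
the unweighted mean pixel position of keypoints with confidence at or above
`min_confidence` (default **0.1**, which excludes undetected parts encoded
as `(0, 0, 0)` while keeping genuinely low-confidence detections). A pose
in frame *t* is then associated with the pose in frame *t + 1* whose centre
of mass is nearest in Euclidean distance — equivalently, one K-means
assignment step with the frame-*t* centroids as fixed cluster centres.

Design points:

* **One-to-one matching.** Nearest-centroid alone can map two poses onto
  one successor. The default resolves conflicts greedily in ascending
  distance order; `method = "optimal"` minimises total distance by exact
  enumeration (scenes of interest hold a handful of people, so
  permutation enumeration up to 8 poses suffices; no assignment-problem
  solver is available in the target environment, and none is needed at
  this scale). Ties break toward the lower pose index in frame *t + 1*,
  for determinism.
* **Gaps.** A pose with no predecessor starts a new track; a track with no
  successor terminates. There is no re-identification across gaps: a person
  missing for even one frame returns as a new track. Downstream, missing
  *keypoints* (below-threshold confidence) are linearly interpolated over
  runs of at most `max_gap = 5` frames (21 ms at 240 Hz); longer gaps are
  an error at reconstruction time, because silently bridging long occlusions
  would fabricate data.
* **Subject selection.** When several people are in view (kicker,
  goalkeeper), the kicker is taken as the longest track, optionally
  restricted to a pixel region of interest, and the choice is logged.

The brute-force all-pairs assignment is kept as an independent oracle in
the tests; the packaged associator must agree with it exactly on random
frames with up to six poses.

## Camera model and 3D reconstruction

Each camera is an 11-coefficient **Direct Linear Transformation**:
`u = (L1·X + L2·Y + L3·Z + L4) / (L9·X + L10·Y + L11·Z + 1)` and analogously
for `v`. Calibration solves the two linear equations per control point by
least squares with the 12th coefficient normalised to 1, after Hartley-style
centring/scaling of both image and world coordinates (a pure conditioning
device: the returned coefficients are de-normalised, and calibration from
fewer than 6 points or a near-coplanar cloud — condition number above 1e8 —
is refused). No nonlinear refinement is applied: with the distortion
handled separately the residual problem is genuinely linear.

**Radial distortion** follows the two-coefficient Brown model about a
configurable centre (default: image centre):
`distorted = c + (1 + k1·r² + k2·r⁴)(ideal − c)`. Undistortion inverts this
by fixed-point iteration on the radial scale (tolerance 1e-8 px, at most 50
iterations, error on non-convergence). Correction is applied **before**
calibration and before triangulation, so the DLT always sees ideal pixels.

**Triangulation** stacks the two DLT equations per camera for all observing
cameras (at least two) and solves for the world point by least squares; the
RMS reprojection residual is attached to every sample, and near-parallel
viewing rays trigger a warning. The **global calibration error** reconstructs
every control point from its own image observations and reports per-axis
mean absolute deviation from the reference coordinates (MAE per axis, with
RMSE alongside; MAE is used for consistency with the agreement statistics).

World frame: x antero-posterior (toward the goal), y medio-lateral,
z vertical; origin at a corner control point; metres internally,
centimetres only in reports.

## Trajectory smoothing

Raw reconstructed trajectories are treated per axis with a dual filter:

1. **Zero-phase Butterworth**, order 4, cutoff 25 Hz at the sampling rate
   (default 240 Hz). Forward–backward application removes phase lag, which
   matters because event-locked quantities (impact speed) would otherwise
   shift in time. No cutoff compensation for the double pass is applied;
   the 25 Hz figure names the design cutoff of each pass.
2. **Robust local quadratic regression** (rloess): for every sample a
   quadratic is fitted over the `span` nearest neighbours with tricube
   distance weights, iterated five times with bisquare robustness weights
   computed from the residual median (scale 6·MAD). `span = 0.1` is a
   fraction of series length.

Numerical choices that required care:

* **IIR start-up.** The Butterworth pass removes the straight line through
  the series endpoints before filtering and restores it afterwards, and
  pads both ends by odd reflection. The filtered signal then vanishes at
  the boundaries, killing the infinite-impulse-response start-up transient;
  constants and rigid translations pass through exactly (asserted in the
  tests).
* **Robustness degeneracy.** On noiseless, smooth input the residual MAD can
  be tiny while residuals are *structured* (lack of fit at high-curvature
  segments), and naive bisquare iteration then deletes the fastest part of
  the kick. Two guards prevent this: a window whose robustness weights all
  vanish falls back to plain tricube weights, and robustification stops
  early when the residual scale is negligible relative to the signal range.
  (`stats::loess(family = "symmetric")` lacks such guards and collapses on
  exactly this input, which is why the smoother is implemented in the
  package.)
* **Boundary order upgrade.** A one-sided local quadratic leaves an O(h³)
  bias on high-jerk segments — and ball contact sits at the last sample.
  Windows that are strongly one-sided therefore fit a local cubic, the
  standard endpoint order correction. This is what brings terminal-speed
  recovery within tolerance.
* **Span is relative.** Because `span` is a fraction of series length, the
  rloess bandwidth widens on long recordings. The filter contract (5 Hz
  passes within 2 %, 60 Hz attenuated > 90 %) is asserted at kick-typical
  lengths of about one second at 240 Hz; at several seconds the loess stage
  begins to attenuate the passband and a smaller span would be appropriate.

## Kick measures

* **Velocity**: central differences at interior samples, one-sided first
  differences at the two endpoints; resultant speed is the Euclidean norm.
* **Foot centre of mass** (`cm_foot`): per-sample centroid of lateral
  malleolus, calcaneus and fifth-metatarsal-head markers.
* **Impact speed**: mean resultant `cm_foot` speed over the three frames
  immediately before ball contact (frames c−3 … c−1); the endpoints' one-sided
  differences never enter this window.
* **Sagittal joint angles**: the included angle between the projections of
  the joint→proximal and joint→distal segment vectors onto the sagittal
  plane, in [0, π] (straight limb = π). The default sagittal plane is the
  global x–z plane of progression; a subject-specific plane normal to the
  inter-hip axis is available (`plane = "hips"`). ROM, being a difference,
  is insensitive to this choice for near-planar kicks. The marker set has
  no trunk proxy, so the hip angle uses a virtual proximal reference
  vertically above the hip; this included angle folds if the thigh crosses
  the vertical, so hip ROM is reported with that caveat while knee and
  ankle ROMs are convention-clean.
* **ROM**: max − min over the analysed window; default the whole cycle,
  window configurable.
* **Time normalisation**: linear interpolation onto 101 points (0–100 %,
  so integer percents are exact grid points) between cycle start
  (kicking-limb take-off) and ball contact. Percents 1–65 are the support
  phase, 66–100 the contact phase; 0 is the unlabelled origin. Events are
  inputs, not detected: phase boundaries come from the study annotations.

## Agreement statistics

All comparisons treat the manual method as reference (`dm`) and the
markerless method as test (`da`).

* **MAE** `(1/n) Σ|dm − da|`, pooled over all frames of all trials within
  each phase, per marker and axis; positions in cm, resultant velocity in
  m/s. The `All` column is the unweighted mean of the three axis MAEs, and
  the `Overall` row the unweighted mean across markers — with the 65/35
  phase split this makes the whole-cycle value exactly
  0.65·support + 0.35·contact, an identity the tests assert.
* **Effect sizes**: Cohen's d with the unweighted pooled SD,
  `(Mm − Ma)/√((σm² + σa²)/2)`; profiles evaluate d at each of the 101
  grid points across trials and report mean/min/max. Labels: trivial
  (< 0.2), small (0.2–0.59), moderate (0.6–1.19), large (≥ 1.2), on |d|.
* **Correlation**: Pearson r, 95 % CI by Fisher z (±1.96/√(n−3),
  back-transformed), two-sided p from the t transform. Magnitude labels
  trivial/small/moderate/large/very large/almost perfect at cuts
  0.1/0.3/0.5/0.7/0.9; a CI spanning both −0.1 and +0.1 overrides the label
  to *unclear*. Shared variance r² is labelled small/moderate/large at
  0.3/0.5.
* **ICC**: the form is a genuine design choice; ICC(2,1) — two-way random
  effects, absolute agreement, single measures — is used because method
  interchangeability is an absolute-agreement question (a constant bias
  between methods should, and does, depress it). The p-value comes from
  F = MSR/MSE.
* **Ratio limits of agreement**: per-pair ratios test/reference, analysed
  on the log scale; systematic bias = geometric mean ratio, random error =
  ×/÷ factor exp(1.96·SD(log ratio)), reported in "g ×/÷ f" notation.
* **Pointwise median ± 95 % CI**: distribution-free order-statistic
  intervals — the narrowest symmetric rank pair (l, n+1−l) whose exact
  binomial coverage reaches 95 % (for n = 30: ranks 10 and 21, coverage
  95.7 %, which the coverage simulation confirms lands in the 94–96 % band).
  With fewer than 6 trials no such pair exists and a seeded percentile
  bootstrap (2000 resamples, default seed 20220121) is used and logged.
  Methods differ significantly wherever the two bands are disjoint;
  contiguous flagged percents merge into intervals reported as
  "from 16 to 18%" or "20% instant".
* **Multiplicity**: none applied across time points or markers, matching
  standard practice for this battery; the report logs the total comparison
  count so readers can judge. Significance threshold p ≤ 0.05 two-sided.
* Trials are treated as exchangeable units in all across-trial statistics;
  a grouping option (players) is deliberately not imposed because the
  per-trial archives carry no subject structure.

## The synthetic world

The generator exists so every stage is testable against known truth without
any external data.

* **Kick**: a planar thigh–shank–foot chain in the sagittal plane driven by
  minimum-jerk joint-angle profiles — smooth, bandlimited well below the
  25 Hz cutoff, and analytically constructed so each programmed ROM is
  attained *exactly* inside the cycle (knee flexion peaks at 82 % of the
  cycle and re-extends with its angular-velocity peak at ball contact;
  the ankle plantarflexes into impact; the thigh swings from extension into
  flexion). Defaults: thigh/shank/foot 0.45/0.42/0.25 m, knee ROM 1.9 rad,
  ankle 1.4 rad, hip 1.1 rad, terminal foot speed 20 m/s, 200 frames at
  240 Hz — magnitudes chosen to match published real-kick values. The
  pelvis translates forward with a ramped speed profile whose terminal
  value is calibrated (deterministic fixed-point iteration) so the mean
  `cm_foot` speed over the three pre-contact frames equals the programmed
  terminal speed; rotation supplies most of the foot speed and the pelvis
  absorbs the remainder, which makes the pelvis faster than a real one —
  a knowing simplification, since only the distal kinematics are under
  test. Events are emitted at frames 0, round(0.65·n) and n−1.
* **Rig**: four pinhole cameras, one per side of the 3.6 × 3.2 × 1.3 m
  calibration volume, perpendicular optical axes, 2.5 m outside the nearest
  face, 1.2 m high, aimed at the volume centre; 1920 × 1080 at 240 Hz,
  focal length 600–800 px (wide-angle action-camera regime), Brown
  distortion k1 = −1.2e−7 px⁻², k2 = 2e−14 px⁻⁴ (≈ 4 % barrel pull-in at
  600 px radius). A 2 cm seeded placement jitter breaks perfect symmetry.
  The 49-point calibration frame is a 7 × 7 lattice with heights cycling
  through three levels, spanning the volume exactly and non-coplanar by
  construction.
* **Rendering**: markers project through the true cameras with forward
  distortion; detection noise is Gaussian with chosen SD; confidences are
  Gaussian around 0.9 (SD 0.05, clipped to [0, 1]); out-of-frame markers
  get confidence 0 (occlusion emulation). The remaining 19 BODY_25
  keypoints come from a plausible static body template riding on the
  mid-hip, so full-pose centroids behave realistically for tracking.
  Multi-trial scenes draw each kick's ROMs and terminal speed within ±5 %
  of the spec (trial-to-trial variability).
* **Multi-person scenes**: independent bounded random walks of full-pose
  templates with known identities and shuffled within-frame order;
  `spacing > 2 × displacement` defines the regime where nearest-centroid
  tracking is provably swap-free, and that guarantee is what the tests and
  acceptance script check.

What the synthetic world does **not** emulate — and what passing tests
therefore cannot show about real data: the systematic anatomical offset
between taped markers and pose-estimator joint centres (the generator makes
them coincide, so method error isolates the pipeline); motion blur and
appearance-dependent detection failure (noise is homoscedastic Gaussian);
camera desynchronisation (streams are frame-locked; an integer per-camera
frame offset is accepted in configuration); and ball or goalkeeper
interaction. One visible consequence: with 1 px detection noise the full
synthetic pipeline reaches position MAEs of roughly a millimetre —
an idealised four-camera rig with coincident marker definitions is simply
far more accurate than real markerless capture, whose published errors are
centimetre-scale precisely because of the effects listed above.

## Problem sizes and determinism

The test suite and acceptance script use: 1000 random in-volume points for
the geometric loop; 50 seeded replicates for the camera-count study at
0.5 px noise; 100 multi-person scenes (3 people, 30 frames) and 1000 random
association frames; 1000 random paired datasets for the statistics oracles
(n = 10–60 each) plus n = 10 000 for the log-normal RLOA check; 10 000
replications at n = 30 for CI coverage; and one full 200-frame, 4-camera
kick for end-to-end recovery. Every stochastic step takes an explicit seed;
generators are bitwise-reproducible under a fixed seed, and the pipeline
writes a run log with versions, seed and parameters.

## Known limitations

* Hip-angle ROM depends on the vertical-reference convention and folds when
  the thigh crosses vertical; knee and ankle ROMs are convention-invariant.
* No cross-camera person re-identification: the subject is selected per
  camera by track length/region.
* No event detection: cycle start, touchdown and ball contact are inputs.
* The CI-overlap rule is the only curve-level inference offered — no
  statistical parametric mapping, and no minimal-detectable-change
  estimation (impossible without repeated sessions).
* Intrinsic/extrinsic decomposition of the DLT and bundle adjustment are
  out of scope; the 11-parameter linear model plus separate radial
  distortion is the whole camera model.
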