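---
title: "Validating markerless gait capture: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless gait capture: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitverify)
```

## The measurement problem

A markerless motion-capture (MMC) rig of the kind this package models
combines a 2D pose estimator (COCO-17 keypoints) with depth cameras: each
camera produces per-frame 3D positions of 17 body landmarks at 30 Hz, in its
own coordinate frame, with a confidence score per detection. Validating such
a rig against marker-based motion capture (MOCAP) raises three distinct
questions, and the package mirrors that structure:

* **Kinematics** — can hip and knee flexion/extension be recovered from the
  fused keypoint streams? (`to_world()`, `fuse_keypoints()`,
  `angles_from_skeleton()`)
* **Agreement** — how close are the markerless angles to the reference
  system's, over the whole waveform and at its extrema?
  (`accuracy_report()`)
* **Reliability** — does the system reproduce its own measurements a week
  later? (`reliability_report()`)

The reference data of a real validation study are human recordings that are
not redistributable, so the package carries a synthetic generator whose
ground truth is known exactly; the statistics layer is identical whichever
source the data come from.

## The kinematic chain and its conventions

World frame: X is the walking direction, Y mediolateral (left positive),
Z up. Angles are computed by the *vector method* directly from keypoints:
the vectors from the joint to its two neighbours are projected onto the
sagittal plane (normal `c(0, 1, 0)`) and the flexion angle is 180° minus
their included angle, signed by the cross product so that flexion is
positive. The hip uses the shoulder–hip–knee chain, the knee the
hip–knee–ankle chain. Four conventions were genuinely open and are fixed as
follows, each with an escape hatch:

* **Projection.** Reported sagittal angles could come from projected vectors
  or from the full 3D included angle; projection is the default
  (`project = FALSE` selects the unprojected variant). Under the projected
  convention, angles are invariant to rigid transforms that preserve the
  sagittal plane (translations, rotations about Y); the unprojected
  magnitude is invariant under any rigid transform. The test suite pins both
  properties.
* **Trunk landmark.** The hip angle needs a trunk direction; the same-side
  shoulder is used (`hip_reference = "shoulder_midpoint"` available). A
  forward shoulder offset of `d` therefore tilts the measured hip angle by
  `atan(d / trunk_length)` at every phase — exactly the constant-offset
  mechanism the offset correction exists for, and the mechanism used to
  inject known biases in validation runs.
* **Fusion rule.** Multi-camera merging is a confidence-weighted mean after
  excluding cameras farther than 0.15 m from the per-keypoint median
  (`gate` argument). It degrades gracefully: one camera passes through
  unchanged, one bad camera among three is voted out.
* **Filtering.** A zero-phase (forward–backward) Butterworth low-pass,
  order 4, 6 Hz cutoff, applied to the raw keypoint trajectories — not to
  the angle waveforms — before angle computation. Zero-phase application
  avoids the group delay that would bias event timing. Gaps of up to 3
  frames in a fused trajectory are linearly interpolated; longer gaps or
  less than 90% presence of a required keypoint fail loudly rather than
  impute.

## Cycle segmentation and discrete parameters

The two systems are segmented by their native events: minimum knee flexion
for the markerless stream, upward 20 N crossings of vertical GRF (0.3 s
refractory period) for the reference. Each inter-event interval is linearly
resampled to 101 points (0–100% gait phase, the field convention); partial
cycles are discarded. Cycles are compared per system on the common phase
grid — 30 Hz and 100 Hz streams cannot be compared sample-by-sample in time.

Knee-minimum detection ranks candidate minima by depth and accepts them
greedily under a minimum separation of 0.6 × the expected cycle duration.
When no expected duration is supplied it is estimated from the
autocorrelation; because the true period is rarely a whole number of
samples, integer-lag quantization can score a *multiple* of the period
slightly above the fundamental, so the estimator takes the smallest local
autocorrelation peak within 80% of the best peak rather than the argmax.

Discrete parameters (max, min, ROM per joint) average per-cycle extrema
across cycles (`average = "per_cycle"`); taking extrema of the mean curve is
available as `average = "mean_curve"`. The two differ in the presence of
cycle-to-cycle variability, and averaging extrema is the literal reading of
"averaged maximum/minimum". ROM is defined as max − min, so it is exactly
invariant under any constant offset.

## Agreement statistics

All covariances and standard deviations use n − 1 denominators.

* **Waveform RMSE**: per participant over the 101-point grid between the two
  systems' mean waveforms, then mean and SD across participants.
* **Lin's CCC**: `2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`, penalizing location
  and scale shifts as well as decorrelation; CI via the Fisher z-transform
  with Lin's asymptotic standard error. `|CCC| ≤ |r|` always, with equality
  when means and variances match. For waveform agreement the CCC is pooled
  over all participants' waveform samples (a per-participant CCC is not well
  defined when a participant's two waveforms are nearly identical).
* **Bland–Altman**: differences are markerless − reference; limits of
  agreement are bias ± 1.96 sd, so the bias is always the midpoint of the
  limits and the width is exactly 2·1.96·sd — both identities are asserted
  in the tests.
* **ICC(2,1)**: two-way random effects, absolute agreement, single measures,
  computed from the mean squares of the subjects × sessions decomposition;
  the CI is the McGraw–Wong F-based interval with Satterthwaite degrees of
  freedom. The closed form is cross-checked against an explicit
  `stats::aov()` decomposition (10⁻¹⁰ agreement on 1000 random instances)
  and against an independent implementation on frozen fixtures.
* **SEM** = sd·√(1 − ICC), with sd pooled over all measurements of both
  sessions (the natural choice when neither session is privileged).
* **MDC**: two factor conventions coexist in the literature. The textbook
  MDC95 is 1.96·√2·SEM. The published reliability table bundled with this
  package (`reference_table("reliability_params")`) instead satisfies
  MDC ≈ 1.96·SEM/√2 (≈ 1.386·SEM) in every cell, so that factor — the
  `"ratio"` convention — is the default, making reports arithmetically
  consistent with the table they mirror; `"conventional"` selects the
  textbook factor. Neither is asserted as "correct": they differ by exactly
  a factor of 2 and the choice is a reporting convention. One cell of the
  bundled table (knee ROM at 1.0 m/s: SEM 2.20, MDC printed 3.00 where the
  factor gives 3.05) deviates beyond printing precision; the consistency
  check tolerates that single printed cell and nothing larger.
* **Offset correction**: the constant offset between systems (mean waveform
  difference per participant and session) is subtracted from the markerless
  stream before the corrected statistics. The corrected residual has exactly
  zero mean; maxima and minima shift by the offset; every ROM statistic is
  bit-identical between corrected and uncorrected reports.

Degenerate inputs (zero variance where a correlation is requested, zero
total variance for the ICC) raise classed errors rather than returning NaN.

## The synthetic generator

Hip and knee waveforms are truncated Fourier series (H = 4 by default) in
gait phase. The default shapes are sculpted from smooth periodic bumps to
reproduce the canonical anatomy of adult treadmill gait — hip flexion
roughly −10° to +30° peaking near heel strike, knee flexion with a stance
peak near 20° and a swing peak near 55°, exactly two local maxima per
cycle — and are rotated at construction so the knee global minimum falls
exactly at phase 0. That anchor makes the two segmentation routes agree by
construction: ground-truth cycle starts, knee-minimum events and GRF
onsets all coincide at multiples of the cycle duration. Cycle duration
decreases and amplitudes grow with belt speed.

The skeleton is a sagittal-plane chain (vertical trunk, thigh rotated by the
hip angle, shank by the knee angle; left side half-a-cycle out of phase;
head and arms at fixed offsets) built so that re-deriving the angles with
the package's own vector method returns the model waveform exactly — the
self-consistency that makes end-to-end recovery testable. A small rigid
whole-body oscillation adds realism without touching any angle.

Observation errors mirror the known failure modes of pose+depth systems:

* isotropic Gaussian keypoint noise (default sd 10 mm — published pipelines
  report no canonical value, so this is the generator's choice of a
  realistic magnitude);
* constant per-joint center offsets (pose estimators mislabel joint centers
  systematically, e.g. the hip);
* a depth-surface bias (default 20 mm) pulling each point toward the
  observing camera along the camera-to-point ray, because depth sensors see
  the body surface nearest the camera rather than the internal joint center;
* keypoint dropout (default 2%, absent coordinates with confidence 0).

Per-participant variation draws an amplitude scale (sd 0.07), a waveform
offset (sd 2°), a cycle-duration factor (sd 0.04) and stature
(1.75 ± 0.10 m); session 2 re-uses the participant's parameters with a small
extra perturbation (amplitude sd 0.015, offset sd 0.3°), giving waveform
changes well under a degree — a test–retest structure in the
"good-to-excellent" reliability regime. All perturbations are
amplitude-scale-plus-offset transforms, which are monotone in the waveform
value and therefore preserve the knee-minimum anchor exactly.

What the generator does **not** emulate: soft-tissue artefact dynamics
(offsets are constant, real ones move), pose-estimator errors correlated
with viewpoint or self-occlusion, trunk lean and arm swing (the trunk is
vertical by construction, so the simulated hip angle is the thigh elevation
angle), inverse-kinematics smoothing on the reference side (reference
angles are truth plus white noise), and out-of-sagittal-plane motion.
Passing the simulation-based checks therefore demonstrates that the
*pipeline and statistics* are correct and that known injected biases are
recovered and removed — not that any physical rig meets the published
accuracy bands on real bodies.

## Numerical choices and problem sizes

* Filter edge transients: 0.5 s is trimmed from each end of the markerless
  angle stream before segmentation.
* The GRF profile rises as √(phase) at stance onset so a 20 N threshold is
  crossed within a fraction of a millisecond of the true event; detected
  crossing times are refined by linear interpolation between samples.
* Default trial length is 60 s (a realistic steady-state treadmill bout
  that keeps a 90-trial study desk-sized); the self-consistency and
  bias-recovery studies in the tests and the acceptance script use 20 s
  trials with 2–5 participants, and the reliability-band check uses the
  full default study (15 × 2 × 3 at 60 s).
* Table rendering rounds to 2 decimals with round-half-even and formats
  cells as `"value (low high)"`; missing cells render as an em dash with a
  warning.

## Interfaces

The package is function-first: `generate_study()` → `analyze_study()` →
`reliability_report()` / `accuracy_report()`, or `run_validation_study()`
for the whole chain, with `render_table()`, `tidy()`, `glance()` and
`autoplot()` on the results. File exchange uses plain formats: long keypoint
CSV, two-column GRF CSV, TRC for marker trajectories (binary C3D is out of
scope), and a CSV of camera extrinsics (`p_world = R p_cam + t`). These
functions and formats, together with this vignette, are the package's user
interface; no shell wrapper is provided because every entry point is a
single R call on tabular inputs.

## Known limitations

* Only sagittal hip and knee angles: the COCO-17 schema has a single foot
  keypoint, so ankle kinematics are not computable.
* Fusion assumes frame-aligned cameras at a common rate; genuinely
  asynchronous rigs would need resampling upstream.
* The ICC confidence interval relies on the usual two-way ANOVA normality
  assumptions; with n = 15 participants it is approximate.
* The bundled published summary tables are inputs for arithmetic
  consistency checks, not a benchmark the simulator is fitted to.
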