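---
title: "Methods: simulated vestibular gait, ZUPT stride estimation, and subject-wise evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated vestibular gait, ZUPT stride estimation, and subject-wise evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vestigait)
```

This vignette documents the models, assumptions and design choices behind
`vestigait`. The package implements a complete analysis chain for
IMU-based vestibular gait screening — synthetic cohort generation, axis
alignment, filtering, zero-velocity-update (ZUPT) stride estimation, a
590-feature descriptor scheme, subject-wise Random-Forest evaluation, and
cluster-level interpretation — and this document explains *why* each stage
is built the way it is.

## The synthetic cohort generator

No public dataset accompanies the screening problem the package targets,
so the generator in `simulate_cohort()` is a first-class, tested component
rather than a fixture. It emulates a two-class gait study: `n_per_class`
(default 15) participants per class, seven walkway tasks, three trials per
task, 13 IMU placements streaming tri-axial acceleration (m/s²) and
angular rate (rad/s) at 128 Hz. Each trial starts with `static_lead_in`
(2 s) of quiet standing followed by periodic straight-line gait.

**Foot kinematics.** Each foot alternates stance (ground-truth velocity
exactly zero) and swing. Swing-phase forward velocity is a raised cosine,
`v(τ) = (L/S)(1 − cos 2πτ/S)` over swing duration `S = 0.4 T`; it is C¹ at
the stance boundaries, which keeps numerical integration well-behaved and
makes the stance/swing transition unambiguous, and it integrates exactly
to the drawn stride length `L`. Acceleration is its analytic derivative. A
single-lobed foot pitch rotation accompanies each swing so the stationary
detector sees both criteria fail during swing.

**Arm swing carries the class contrast.** The arm gyroscope's pitch
component is a sinusoid at stride frequency whose integrated range equals
the drawn per-trial pitch range. Left-arm draws come from
`arm_pitch_range` / `arm_pitch_range_sd` — defaults 0.49 (SD 0.21) rad for
controls and 0.26 (SD 0.11) rad for the vestibular class, the eyes-closed
contrast the study design is built around; the right arm uses a smaller
fixed contrast (0.35/0.14 vs 0.26/0.11). Per-participant offsets are drawn
once (SD = class SD/√2) with the remaining variance at trial level, so
trials of one participant are correlated — without that, subject-wise
splitting would be indistinguishable from trial-wise splitting and the
leakage tests would be vacuous. Draws are floored at 0.15 rad so the pitch
axis always dominates the roll axis and the PCA alignment stays
identifiable. Roll sway is drawn from one distribution for both classes
(mean 0.13, SD 0.04 rad, capped at 0.8 × pitch): roll is deliberately
non-discriminative, which the Welch stage should rediscover.

**Task differentiation.** Only the speed tasks and the eyes-closed task
are kinematically distinct: eyes-closed applies the class contrast at full
strength, all other tasks at 0.35 of it; slow/fast tasks scale stride time
and length (×1.3/0.7 and ×0.85/1.15); head-turn tasks add a square-wave
head rotation (period three steps) with no extra class contrast. This is
the minimum structure needed for the expected task ordering (eyes-closed
strongest) to be a property of the data rather than of the code under
test. Walking-speed distributions per task are not derivable from
published summaries; the defaults (control stride 1.25 m / 1.05 s,
vestibular 1.05 m / 1.15 s, with half-gap participant effects) are chosen
once as typical adult walkway values with a plausible slowing in the
vestibular class.

**Sensor imperfections.** Each placement gets a small random mounting
rotation (rotation-vector SD 0.05 rad by default) — forcing the alignment
stage to do real work — plus white noise (accelerometer 0.05 m/s²,
gyroscope 0.02 rad/s) and a per-axis gyro bias growing linearly in time
(slope SD 0.001 rad/s per s). The linear bias matches the ZUPT scheme's
linear-drift assumption, so correction is exactly achievable in the
noise-free limit. Head, trunk and leg sway amplitudes share a
participant- and trial-level log-normal scale factor; accelerometers away
from the feet measure only gravity plus noise, so acceleration features
are class-uninformative by construction and the interpretation stage has a
known right answer.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: turn-arounds on a short walkway, double-support
dynamics and ground-impact transients, magnetometer output, arm dynamics
in the accelerometer, task-to-task fatigue, or the clinical heterogeneity
of vestibular diagnoses (BPPV vs hypofunction subtypes are out of scope).
Results on the synthetic cohort are structural checks of the pipeline, not
clinical performance estimates.

## Axis alignment

The gravity axis is the mean static-segment acceleration direction; a mean
norm below 0.5 g raises an error (the sensor was moving). The frontal axis
is the first principal component of the walking-segment angular velocity
projected onto the plane orthogonal to gravity; an eigenvalue ratio below
1.05 raises an ambiguous-axes error rather than guessing. PCA leaves a
sign ambiguity; the package fixes it by requiring the mean angular
velocity about y to be non-negative over the walking segment. Any such
convention is arbitrary, but it must exist — minimum and maximum of signed
axes are features — and it is applied identically to both classes. The
first `static_lead_in` seconds are taken as the static period; no detector
is attempted.

## Filtering and sway

All descriptor features are computed on a zero-phase band-passed walking
segment (4th-order Butterworth, 0.5–25 Hz, forward–backward via
`filtfilt`; the input is demeaned first to suppress edge transients).
Sway displacement is the cumulative trapezoidal integral of the *filtered*
angular rate, so it is implicitly high-pass detrended and bounded; its
range is therefore the pure-tone filter gain times the geometric range for
a sinusoidal swing — a few percent below the unfiltered range at typical
stride frequencies (~0.9 Hz, near the 0.5 Hz corner). The tests encode
this with a closed-form `|H(f)|²` oracle rather than pretending the filter
is transparent.

## ZUPT stride estimation

Stationary samples satisfy `| ‖a‖ − g | < 0.8 m/s²` and
`‖ω‖ < 0.6 rad/s` on the *raw* body-frame signals (the band-pass removes
gravity and would destroy the first criterion). Runs shorter than 0.08 s
are discarded; runs separated by less than `min_stride_time` are merged;
each surviving run contributes one footfall anchor at its midpoint (the
footfall instant is not otherwise defined). `min_stride_time` defaults to
0.3 s: the merge window must stay below the shortest swing duration
(≈ 0.36 s on fast trials) or true stances get merged away; all four
thresholds are exposed in `stationary_thresholds()`.

Between anchors, gravity is subtracted along body z, acceleration is
integrated to velocity, and the line through the integrated velocities at
the two bounding anchors is subtracted — the exact correction when the
velocity error is linear in time, i.e. when the underlying acceleration
error is constant between footfalls. Corrected velocity is zero at every
anchor by construction. Stride length is the planar (x–y) displacement
between consecutive anchors (walking is level), stride time the anchor
spacing, stride frequency the mean of 1/stride time, and foot speed the
planar path length divided by elapsed time. Trials with fewer than two
anchors yield zeroed spatiotemporal features with a warning instead of
aborting: cohort assembly must be total, and a degenerate trial is a data
problem to surface, not a reason to lose the dataset.

## Features

Per placement: 5 descriptors × (3 gyro + 3 accel axes + 2 total
magnitudes) = 40, plus mean and range of pitch and roll sway = 44; head
and trunk placements add the 95% confidence-ellipse areas of
(ω_pitch, ω_roll) and (θ_pitch, θ_roll), computed as
`π · χ²₂(0.95) · √det(Σ̂)` with `χ²₂(0.95) = 5.991` (46); feet add stride
length mean/variance, stride time mean/variance, stride frequency mean and
foot speed mean (50). The identity 8 × 44 + 3 × 46 + 2 × 50 = 590 is
asserted at specification construction. Descriptors use the filtered
signals; stride features use the raw signals through the ZUPT path; the
static lead-in is excluded from all feature windows. A degenerate sway
covariance yields area 0, not an error.

## Evaluation protocol

Models are evaluated with 50 repeated subject-wise splits: each repeat
holds out 3 participants per class (6 of 30, an 80/20 split by
participant), drawn independently so participants recur across repeats —
unavoidable with 50 repeats over 30 participants. Standardization
(mean 0, population SD 1) is fit on the training split only;
zero-variance features map to 0 on both sides. Hyperparameters (number of
trees, max features, max depth, min node size) are tuned by participant-
grouped 5-fold CV on the training split, optimizing AUROC, ties broken by
grid order; `fast_model_config()` provides a single sensible grid point
(500 trees, √p features, unbounded depth) for studies where the tuning
grid is not the object of interest. Held-out probabilities are pooled over
all repeats and summarized by the merged AUROC (midrank ties) with a
1,000-resample percentile bootstrap CI, and threshold-0.5 metrics.

A calibration note: with 30 participants, the merged AUROC of a single
label-permuted dataset has a standard deviation near 0.1 (trials within a
participant are correlated), so the package's chance-level checks average
over several independent participant-level permutations instead of
trusting one draw.

## Interpretation

Feature multi-collinearity is summarized by Ward clustering
(`ward.D2`) on the 1 − |Pearson ρ| distance, cut at 3 clusters by default
(configurable). Importance is measured per cluster: all features of a
cluster are shuffled with one *shared* row permutation — preserving the
intra-cluster correlation the clustering was built to respect, where
independent per-feature shuffles would break it — and the drop in test
AUROC is averaged over 100 permutations with a percentile CI. Negative
drops are reported as-is; they are noise, and hiding them would overstate
certainty. Welch t-tests on the top cluster use the
controls-minus-vestibular sign convention and report
`r = √(t²/(t² + df))`; this effect-size formula is adopted because it
reproduces the published effect sizes from their own t and df values to
two decimals in the verification suite.

## Orchestration and problem sizes

`run_experiment()` ties the stages into the placement × task grid and
writes CSV/JSON artifacts stamped with a configuration hash; a rerun with
the same configuration is byte-identical. The default grid evaluates one
IMU per segment class — head, upper back, lower back, left arm, left
wrist, left shank, left foot — a convention (left side preferred because
the headline single-IMU contrast sits on the left arm), overridable in
`experiment_config()`. The package's own test and acceptance runs use the
full 30-participant cohort for the headline eyes-closed analyses and
smaller cohorts (4–8 per class, 6–25 split repeats) for structural and
property checks; Monte-Carlo checks of the sway ellipse use 10⁵ samples.

## Known limitations

Straight-line gait only; no turn segmentation, so sway features on a real
short walkway would mix turning into the estimates. The stationary
thresholds are tuned on the generator and will need re-tuning for real
sensors. The merged-AUROC protocol assumes reasonable probability
calibration across repeats. The binary design does not address
distinguishing vestibular gait from other sensory or neurological gait
disorders.
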