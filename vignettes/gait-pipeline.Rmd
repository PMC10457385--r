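---
title: "Foot-mounted IMU gait analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foot-mounted IMU gait analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridekit)
```

## The measurement problem

A single IMU strapped to the instep records tri-axial angular velocity and
specific force during a walking test. The analysis must recover, per
stride, where the foot went and when each gait event happened, despite
three compounding difficulties: the sensor frame rotates with the foot, the
accelerometer measures gravity plus motion, and double integration of
noisy, biased acceleration diverges within seconds. The pipeline handles
these in order: orientation estimation, gravity removal, and
zero-velocity-update (ZUPT) drift correction anchored at the instants the
foot is known to be still.

The sensor axes follow the foot-mounted convention (X lateral, Y frontal
toward the toes, Z vertical when the foot is flat); the global frame has Z
up. **Pitch** is the elevation of the sensor Y axis above the global
horizontal plane, positive toe-up (dorsiflexion). Under this sign
convention the heel-strike lands toe-up — the pitch **maximum** of each
motion segment — and the toe-down push-off is the pitch **minimum**. Both
assignments are exercised against the simulator in the unit tests; a user
with the opposite hardware convention can negate pitch upstream.

## Orientation: Mahony complementary filter

The sensor-to-global rotation is propagated by integrating the gyroscope
with the exact quaternion exponential of the per-step rotation increment,
and corrected by the accelerometer's gravity observation: the correction
term is the cross product between the normalised accelerometer reading and
the estimated gravity direction in the sensor frame, fed back with a
proportional gain `kp` and an integral gain `ki` (gyro-bias tracking).

Gains default to `kp = 0.5` s⁻¹, `ki = 0.01` s⁻². There is no published
value to match; `kp = 0.5` gives a ~2 s correction time constant — fast
enough to hold attitude through a walking bout whose stance phases
re-anchor the gravity direction roughly once per second, slow enough not
to chase the (non-gravitational) swing acceleration too eagerly. During
swing the accelerometer briefly observes motion rather than gravity and
the attitude error grows to one or two degrees, which misprojects a few
tenths of m/s² of gravity into the horizontal channels; the ZUPT stage
absorbs the integrated effect, and the end-to-end recovery tests bound the
residual error at about one percent of stride length.

Initial orientation comes from the protocol's initial standstill: the mean
accelerometer vector over the first seconds (`align_window = 2` s) fixes
roll and pitch; yaw is unobservable from gravity and set to zero. Every
quantity the pipeline reports (pitch, displacement norms, path lengths) is
invariant to that choice.

## Segmentation and events

Zone classification thresholds the gyroscope magnitude, smoothed by a
0.05 s moving average to suppress single-sample crossings:

* **still**: magnitude < 0.2 rad/s sustained for ≥ 1 s — the subject is
  standing, outside any walking bout;
* **movement**: magnitude > 1.41 rad/s — opens a walking bout (a bout is
  any stretch between still intervals containing at least one movement
  sample);
* **foot-flat**: magnitude < 0.5 rad/s for ≥ 0.05 s *inside* a bout — the
  mid-stance dwell.

The minimum durations are debounce choices at 104–128 Hz: a genuine
foot-flat lasts several hundredths of a second even in fast gait, and a
genuine stop lasts over a second. A consequence worth knowing: the dwell
after the final cycle of a bout merges with the subsequent standstill into
one still interval, so the last cycle contributes no stride — the
simulator accounts for this when it constructs its ground truth, adding
lead-in/lead-out cycles around the requested stride count.

Events: within each motion segment between consecutive foot-flat
intervals, toe-off = pitch minimum and heel-strike = pitch maximum, both
required to be interior and ordered (toe-off first); toe-strike and
heel-off are the foot-flat boundaries. Monotone pitch in a segment
therefore yields no events rather than spurious ones. Strides are
heel-strike to heel-strike, which makes the four phase percentages — load
(HS→TS), foot-flat (TS→HO), push (HO→TO), swing (TO→next HS) — sum to 100
exactly, an identity the acceptance suite checks to 1e-6 across hundreds
of simulated strides.

## Strapdown integration and ZUPT

Gravity-free global acceleration is integrated twice with the trapezoid
rule (`dt` from the clock-corrected timestamps). Between consecutive
zero-velocity anchors, the raw velocity's drift is removed by subtracting,
per axis, the straight line through the anchor values; this is exact for
any drift affine in time and leaves velocity exactly zero at every anchor.
Anchors default to the **midpoints** of foot-flat intervals (where the
foot is most reliably stationary) plus still-interval midpoints;
`anchor_policy = "endpoints"` is available. Correction is per-axis, not
per-magnitude. After the position integration, the vertical coordinate is
re-zeroed through the anchor heights (piecewise-linear detrend), so
clearance — the maximum vertical excursion during swing — is measured from
the stride's own ground level rather than from a drifting altitude.

## Per-stride metrics and filtering

Fourteen quantities per stride; three identities hold by construction and
are asserted for every emitted stride: phase percentages sum to 100,
`cadence × stride_time = 60`, `speed × stride_time = stride_length`.
Stride length is the horizontal (XY) endpoint displacement; the 2D/3D path
lengths are cumulative displacements, so `path3d ≥ path2d ≥ stride_length`.
Clearance uses the vertical (Z) axis during the swing window only.

The stride filter keeps a stride iff its length lies in
`[0.36 × median, 1.4 × median]`, the median taken over **all** detected
strides before any removal. Both bounds are inclusive — the published rule
says "longer than" / "lower than", so boundary values are not outliers —
and the filter is idempotent on its own output. Summary statistics use the
n−1 standard deviation; walking time excludes still intervals.

## Clinical scorers

All scorers are total and deterministic over their domains. Printed bin
edges for the SPPB leave 0.01 s gaps (6.20/6.21, 11.19/11.20, 13.69/13.70,
16.69/16.70 s); inputs are rounded to the instrument's two-decimal
precision before binning so the bins partition the line and no time is
unreachable. The boundary 4.82 s is assigned to the three-point bin
(inclusive lower edge), 60.00 s to the one-point bin, and the tandem stand
needs strictly more than 10 s for two points; each choice is covered by an
explicit boundary test. Records distinguish *incapable* (`NaN`, register
cell `"incapable"`) from *not recorded* (`NA`, cell `"-"`): an incapable
4-m walk or grip test counts as affirmative for the Fried slowness and
weakness criteria (the subject cannot reach any threshold), whereas an
unrecorded value leaves the criterion — and hence the index and category —
undetermined.

## The simulator: what it emulates and what it does not

`simulate_walk()` builds an analytic foot trajectory — initial standstill,
then cycles of a motion phase (minimum-jerk horizontal advance, a single
`sin²` clearance hump, and a smooth pitch oscillation dipping toe-down
then peaking toe-up) followed by a foot-flat dwell, closing with a final
standstill — and synthesises exact sensor streams from it: gyroscope =
true angular rate about the lateral axis, accelerometer = `Rᵀ(a_free + g)`,
plus white noise and constant bias. Because position, velocity, pitch and
its rate are all analytic, ground truth is exact to the sample grid, and
the self-consistency of the streams (numerical derivative of the true
trajectory vs the noise-free signals) is itself under test.

Defaults are chosen once as typical of an older-adult walking test: 1.0 m
strides (SD 3 cm), 1.2 s cycles (SD 4 cm/s-scale), foot-flat fraction
0.35, clearance 0.15 m, pitch +20° at heel-strike / −25° at toe-off, 30 s
initial standstill, 104 Hz, noise σ_acc = 0.05 m/s², σ_gyr = 0.005 rad/s,
biases of ~0.02 m/s² and ~0.002 rad/s. The kinematics are deliberately
minimal: sagittal-plane motion only, no turning, no left–right asymmetry,
no slope, no soft-tissue artefact, no pathological gait shapes. Passing
the recovery tests therefore demonstrates the pipeline's numerical
correctness under its stated assumptions — not its clinical accuracy on
real feet, which would require instrumented-walkway validation.

Test and acceptance runs scale the problem down for speed — short
standstills (1.5–5 s), bouts of 3–20 strides, one hundred bouts for the
invariant sweeps — sizes the package chooses to make the full suite run in
seconds while still crossing every code path; the simulator's scientific
defaults remain the 30 s protocol values.

## Numerical choices and degenerate inputs

* Calibration order is bias-subtract → misalignment → scaling, matching
  the parameter-file naming; any consistent convention reproduces the
  calibrated outputs given matching files. `time_true = time_nominal ×
  clock_error` (the factor is documented as multiplicative; invert it
  upstream if a device defines it the other way).
* The reduced calibration estimator fits the accelerometer bias from the
  quadric through multi-pose means (bias is identified even though the
  quadric family is scale-deficient) and then the per-axis scales with the
  bias fixed; it is flagged experimental and does not attempt misalignment.
* Gravity is 9.81 m/s² throughout.
* Empty inputs fail loudly: an empty stride set cannot be filtered or
  summarised, a metrics file is never written empty, ZUPT refuses fewer
  than two anchors, and a still-only recording raises "no strides
  detected" with the stage name attached.
* Ties in pitch extrema resolve to the first sample (`which.min`/
  `which.max`); at 104 Hz this is at most a 1-sample (≈ 10 ms) ambiguity,
  inside every stated tolerance.

## Known limitations

Heading (yaw) is unobservable without a magnetometer, so absolute 2D paths
are correct in shape locally but may rotate slowly; all reported metrics
are yaw-invariant. The Mahony correction trusts the accelerometer during
swing more than an adaptive-gain filter would; the resulting attitude
ripple is bounded and absorbed by ZUPT but would grow for running gait,
which is out of scope. The stride filter assumes a unimodal stride-length
distribution; bimodal gait (e.g. severe limping recorded on one foot)
could see valid strides removed. Clinical scorers validate ranges but do
not reproduce the question flow of the source instruments (GDS is stored
and validated, not staged; TUG is recorded, not scored).
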