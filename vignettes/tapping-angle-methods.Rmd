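---
title: "Estimating the finger-tapping angle from paired fingertip gyroscopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the finger-tapping angle from paired fingertip gyroscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingertap)
```

## The measurement problem

The finger-tapping test — repeatedly touching thumb and index fingertip as
fast and as wide as possible — is a standard probe of bradykinesia in
Parkinson's disease and related disorders. Clinicians grade it visually;
instrumented versions need a single, interpretable amplitude measure.
`fingertap` implements such a measure from two tri-axial gyroscopes mounted on
the fingernails of thumb and index finger (x axes along the fingers, z out of
the nail): the **tapping angle** `theta(t)`, the angle between the two
fingers' longitudinal axes about the *dominant rotation axis* of the relative
movement, defined to be zero at finger contact and maximal at full opening.

Treating the two distal phalanges as rigid bodies, the package estimates the
rotation matrix `R(t)` that maps thumb-sensor components into the index-sensor
frame, projects the thumb's x axis onto the index finger's x–z plane, and
takes the signed angle `alpha = atan2(r31, r11)` of that projection. The
clinical angle is `theta = -alpha` with the baseline removed. Because only
*relative* motion enters, the hand may move freely during the test.

## Autocalibration

`R(0)` is unknown (it depends on mounting). The measurement protocol
therefore starts with the fingers pressed together while the whole hand draws
circles in the air: both sensors then sense the *same* rotation vector, in
their own frames, so for the correct `R` the transformed thumb signal must
reproduce the index signal. `detect_calibration_window()` finds this phase
automatically — the earliest run in the first half of the recording where both
smoothed magnitudes exceed 30 deg/s while differing by less than 10% for at
least 0.5 s (all thresholds configurable; none is critical, they only locate
the window). `estimate_initial_rotation()` then minimises the summed squared
residual of the rotation equation over the window, parameterised by three
Euler angles so the estimate is orthonormal by construction, using
Nelder–Mead simplex (origin start, tolerance 1e-10, up to 5000 iterations,
plus six deterministic ±45° single-axis restarts when the relative residual
stays above 1e-6 — a cheap guard against local minima). The cost is summed
over *all* window samples rather than evaluated at three instants: with a few
hundred samples the problem is heavily over-determined and white sensor noise
averages out; recovery error on simulated windows is ~1e-4 rad noise-free and
well under 1° at 0.5 deg/s noise.

If the manoeuvre excites only one axis, the rotation component about that
axis is unidentifiable even though the residual is tiny; the estimator flags
this (smallest/largest eigenvalue of the angular-velocity second moment below
1%) instead of failing silently.

## Two estimators and the drift rule

**AL-C (continuous).** At each 5 ms step the relative angular velocity
`wr = R w1 - w2` is formed with the current matrix and `R` is premultiplied by
the exact small-rotation factors `Rz(wrz dt) Ry(wry dt) Rx(wrx dt)`. Exact
trigonometric factors keep the product orthonormal to round-off, so no
re-orthogonalisation is needed (an optional periodic Gram–Schmidt guard
exists). Two numerical properties matter:

* the causal update (increment from the sample at the *start* of each step)
  gives the reported angle a half-sample (2.5 ms) effective time lag — up to
  ~0.6° apparent error at the fastest simulated rates when compared
  pointwise against truth. This is a timestamp convention, not an angle
  error; agreement metrics absorb it.
* the ordered z·y·x factorisation differs from the exact rotation exponential
  at second order (a commutator term `~ ½ v_i × v_j` per step). For
  single-axis-dominant motion — which tapping is, by construction of the
  dominant axis — the defect is negligible; it grows quadratically with
  simultaneous multi-axis rates. The test suite therefore checks AL-C against
  a quaternion oracle in two ways: an independent-algebra mirror of the same
  ordered factorisation (agreement to round-off at any rate), and the true
  exponential-map integrator on moderate streams (per-axis RMS 20 deg/s,
  where the commutator defect stays below 0.1°).

**AL-R (resetting).** Integrating a full matrix drifts when the gyros are
noisy, biased, or clipped. The resetting estimator exploits the observation
that the *second row* of `R` stays practically constant during y-dominant
tapping: it freezes that row at its calibration value, projects the thumb
angular velocity onto y2 through it, and integrates
`wry = r21_0 w1x + r22_0 w1y + r23_0 w1z - w2y` by the rectangle rule. The
matrix is effectively reset every step, so orientation errors cannot
compound; the price is that genuine changes of finger orientation (slips,
re-grips) are invisible to it.

**Selection.** Both estimators run on every sequence. The final drift — the
absolute difference of the raw angle between the start of the trace and the
end of the sequence, two instants at which the protocol guarantees closed
fingers — is near zero for a healthy AL-C run. When it exceeds 60° the
pipeline selects AL-R automatically (strictly greater; at exactly 60° AL-C is
kept).

## Dominant axis and realignment

Per-axis time-integrals of the squared relative angular velocity identify the
dominant rotation axis; in typical recordings y2 dominates (observed regime:
x ≈ 21% and z ≈ 11% of the y integral). When y2 is *not* dominant the index
frame is computationally rotated so the new y2 axis points along the
principal eigenvector of `sum(wr wr' dt)` — the minimal rotation mapping that
axis onto y2, with the sign chosen so that opening counts positive.
Eigen-analysis generalises the per-axis comparison to oblique axes and
reduces to it in the axis-aligned case. Two robustness choices:

* the decision statistic is computed on a 0.1 s moving-averaged `wr`:
  impulsive contact events (impact bounces, thumb slips) can otherwise carry
  more energy than the tapping itself and hijack the axis estimate;
* if no axis reaches 40% of the total energy the movement is deemed
  near-isotropic and the frame is left alone with a warning.

## Tap segmentation and baseline removal

The average tapping period is the lag of the first autocorrelation peak of
the mean-removed angle (searched in 0.2–3 s, prominence ≥ 0.3 of the zero-lag
value). The angle is smoothed by a centred moving average of width
period/8 — wide enough to kill contact bumps and sensor noise, narrow enough
to preserve tap peaks — and tap boundaries are the local minima found by a
heuristic search in windows of ±35% of the period, deduplicated at half a
period. Two pruning rules make the search robust on pathological patterns:
segments whose amplitude falls below `max(2°, 0.2 × median amplitude)` are
merged (flat holds in "skipped tap" patterns would otherwise split), and an
interior boundary sitting more than half the median amplitude above its
neighbours is discarded (a closure must lie near the baseline; wobble dips
during a held-open tap are not closures). Boundaries are finally refined to
the minimum of the *unsmoothed* angle within half a smoothing window, which
cancels any smoothing-induced shift. All thresholds are exposed in
`default_config()` so difficult recordings can be re-segmented manually.

The baseline — per-tap minima connected by straight lines, extended with the
nearest value at the edges — is subtracted, making `theta` exactly zero at
every closure. Per-tap features follow: duration, aperture (max − min within
the tap), and peak opening/closing speeds from central differences.

## Optical reference path

For validation against a motion-capture system, each finger carries a rigid
T-board with three markers (two along local x, one along y).
`board_rotation()` builds the board pose by Gram–Schmidt on the stated
geometry (exact for rigid boards; an SVD/Procrustes fit is available for
noisy markers), the relative rotation is `t(R2) %*% R1`, and the reference
angle applies the same projection. Only a constant offset is applied to the
reference (zero at tapping start) — no baseline removal — mirroring how such
comparisons are reported. The reference is exactly invariant to whole-hand
motion, and a rigidity check flags frames where marker distances deviate by
more than 2 mm.

## Agreement metrics

Agreement is quantified per tap and then averaged per sequence: intraclass
correlation, RMS error, and absolute/relative aperture errors with taps
paired by maximal temporal overlap (reference apertures under 2° are excluded
from relative errors). The ICC form is not uniquely determined by convention
alone; we use the two-way random-effects, absolute-agreement, single-measures
form ICC(A,1), because the two systems are supposed to report the *same
physical angle* — a constant offset between them must count against
agreement. The consistency form ICC(C,1) is available via configuration.

## The simulator: a stated world

`generate_session()` emulates the measurement protocol: 0.5 s closed and
still, 2 s of calibration circles (envelope vanishing before tapping starts,
so the manoeuvre truly ends), then 15 s of tapping. Eleven pattern templates
mirror the clinically observed repertoire: moderate (2 Hz / 40°), fast-wide
(3 Hz / 60°), fast-small (4 Hz / 15°), slow-small (1 Hz / 10°), hand rotation
while tapping (0.2 Hz, 30° roll), tremor (5 Hz / 3°), slow thumb-mount drift
(10° over the sequence), strong impacts (30 Hz damped bounce grazing the
sensor full scale), skipped taps held open or nearly closed (probability 0.1,
one period), and thumb slip at closure (20° about-z, 100 ms). These numbers
are engineering defaults for qualitative clinical labels — they are exposed in
`pattern_spec()` and are not claims about any patient population.

Design choices worth knowing:

* **Raised-cosine pulses** give a C¹ angle (finite gyro rates); skips freeze
  the pulse phase at the open (0.5) or nearly-closed (0.95) position for an
  integer number of periods, so tap counts remain well defined.
* **Cross-axis wobble.** Real tapping is not a pure hinge. Independent
  band-limited oscillations about x and z (near 1.3× and 1.7× the tap rate,
  snapped to multiples of 1/duration so they vanish at both ends) are scaled
  so their rate energies are 21% and 11% of the y energy. Coupling them
  *rigidly* to the tap angle instead would make the commutator defect of the
  matrix update systematically signed and manufacture tens of degrees of
  spurious drift — a lesson that shaped this design.
* **Mounting rotation** (the calibration ground truth) is drawn with a
  dominant y component (±60°) and modest x/z tilts (±15°), reflecting
  nail-mounted sensors with x along the finger. During the preamble the
  *fingers* co-move while the sensor frames differ by exactly this rotation,
  so calibration is non-trivial.
* **Ground truth** is the angle an ideal reference would report — computed
  from the exact relative orientation — not the commanded pulse train. The
  two coincide except where slip/drift events physically perturb the
  projected angle; the commanded train is kept alongside for tap counting.
* **Sensor model**: per-channel constant bias (off by default), bias random
  walk (0.05 deg/s per √s), white noise (0.3 deg/s), clipping at ±2000 deg/s,
  12-bit quantization (step ≈ 0.977 deg/s), all seed-deterministic. Poses are
  differentiated on a 3× supersampled clock before decimation so that
  finite differences do not artificially attenuate high-frequency content.

What a green test does **not** establish: the simulator's rigid two-segment
scissor model ignores finger bending, skin-mounted sensor wobble,
soft-tissue impact dynamics, and any physiological distribution of
amplitudes or rates. Synthetic agreement numbers are surrogates that hold
the pipeline to the published accuracy regime; they are not clinical
validation.

## Numerical and degenerate-input conventions

Radians and rad/s internally; degrees and deg/s in every file format and
report. 1-based inclusive sample indices; times in seconds. The raw angle is
declared undefined when `r31² + r11² < 1e-12` (thumb x parallel to index y)
and the error propagates with a dedicated condition class. Sessions must be
uniformly sampled within 1 µs jitter; isolated missing samples (≤ 25 ms) are
interpolated with a warning, longer gaps are errors. Identical inputs,
configuration and seed reproduce reports bit-identically.

## Known limitations

* Both estimators inherit the half-sample timestamp lag discussed above.
* AL-R systematically reports slightly smaller apertures whenever finger
  orientation changes within a sequence (slip, re-grip) — selecting it only
  under large AL-C drift limits the impact.
* The autocorrelation period estimate assumes a broadly rhythmic sequence;
  severely arrhythmic tapping raises an explicit aperiodic-signal error
  rather than guessing.
* Camera–gyro synchronization for real recordings is assumed handled
  upstream (the simulator emits both on a common clock); only a constant
  offset is configurable.
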