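# fingertap

Quantification of the clinical finger-tapping test from two fingertip-mounted
3D gyroscopes (thumb and index finger).

The finger-tapping test — repeatedly touching thumb and index fingertip "as
wide and as fast as possible" — is how clinicians grade bradykinesia in
Parkinson's disease and related disorders (MDS-UPDRS part III). Visual
grading cannot resolve amplitude differences of a few degrees. `fingertap`
turns two cheap wrist-wearable gyroscopes into an objective instrument: it
reduces the generally three-dimensional relative finger movement to a single
scalar **tapping angle** θ(t) about the dominant rotation axis — zero at
finger contact, maximal at full opening — and extracts per-tap duration,
aperture and peak opening/closing speeds.

## The method

With ω₁, ω₂ the angular velocities sensed in the thumb and index frames and
`R` the thumb-to-index rotation matrix:

* **Autocalibration** — fingers pressed together, hand drawing circles: both
  sensors see the same rotation vector, so `R₀` is estimated by Nelder–Mead
  minimisation of Σ‖ω₂ − R(φx,φy,φz)·ω₁‖² over Euler angles. The calibration
  window is detected automatically (both magnitudes vigorous and practically
  equal).
* **AL-C (continuous algorithm)** — time-steps the full matrix,
  `R⁽ⁿ⁺¹⁾ = Rz(ω_rz Δt)·Ry(ω_ry Δt)·Rx(ω_rx Δt)·R⁽ⁿ⁾` with
  `ω_r = R ω₁ − ω₂`, and extracts the raw angle `α = atan2(r₃₁, r₁₁)`
  (projection of the thumb's long axis onto the index x–z plane);
  `θ = −α` with the baseline removed.
* **AL-R (resetting algorithm)** — freezes the second row of `R₀` and
  integrates `ω_ry ≈ r₂₁⁰ω₁ₓ + r₂₂⁰ω₁ᵧ + r₂₃⁰ω₁_z − ω₂ᵧ`; immune to matrix
  drift, slightly blind to finger re-orientation.
* **Drift rule** — when AL-C's final drift (raw-angle difference between the
  closed-finger start and end of the sequence) exceeds 60°, AL-R is selected
  automatically.
* **Segmentation** — autocorrelation period estimate, averaging filter,
  heuristic minima search; the piecewise-linear baseline through per-tap
  minima is subtracted so θ = 0 at every closure.
* **Validation path** — reference angle from two 3-marker rigid boards
  (`R = R₂⁻¹R₁`), with per-tap ICC (two-way absolute agreement, single
  measures), RMS error and aperture errors.

A rigid-body simulator generates ground-truth sessions for eleven clinically
observed tapping patterns (fast/slow, wide/small, tremor, hand rotation,
thumb-orientation drift, strong impacts, skipped taps held open or closed,
thumb slip) with a realistic gyro model (white noise, bias walk, 12-bit
quantization, ±2000 °/s saturation), so the whole pipeline is testable
without hardware.

## Worked example

Simulate one "fast and wide" session (pattern 2: 3 taps/s, 60° apertures)
and run the full pipeline:

```r
library(fingertap)
ses <- generate_session(pattern_spec(2), seed = 42)
rep <- run_pipeline(ses)
print(rep)
#> <tap_report>
#>   calibration: euler (1.6, 16.1, 12.4) deg, window [0.61, 2.16] s
#>   drift: AL-C 1.9 deg, AL-R 1.7 deg -> AL-C selected
#>   45 taps, mean aperture 59.1 deg, mean duration 0.34 s
#> <tap_agreement> 45 taps: ICC 0.997, RMSE 1.63 deg, aperture err 1.27 deg (rel 0.021)

head(rep$taps[, c("tap_index", "t_start_s", "duration_s", "aperture_deg", "peak_open_dps")], 4)
#>   tap_index t_start_s duration_s aperture_deg peak_open_dps
#> 1         1     2.210      0.625        61.91         621.3
#> 2         2     2.835      0.330        60.36         625.8
#> 3         3     3.165      0.340        55.49         550.2
#> 4         4     3.505      0.330        61.04         606.3
```

Reading the output: calibration recovered the thumb-sensor mounting rotation
from the 0.6–2.2 s co-moving window; AL-C's 1.9° final drift is far below the
60° switch-over, so the continuous algorithm is kept; all 45 commanded taps
were found with apertures near the commanded 60°; and against the simulated
optical reference the per-tap ICC is 0.997 with 1.63° RMS error. The first
"tap" is longer because it includes the quiet lead-in before the first
closure.

A thin command-line surface wraps the same functions
(`inst/cli/fingertap.R`):

```sh
Rscript inst/cli/fingertap.R simulate --pattern 2 --seed 42 --out /tmp/s2
Rscript inst/cli/fingertap.R report --in /tmp/s2_gyro.csv --markers /tmp/s2_markers.csv --out /tmp/s2_report.json
```

## Acceptance script

`scripts/acceptance.R` rebuilds the validation battery from scratch — 22
synthetic sessions (two per tapping pattern) with the default sensor-noise
model — runs autocalibration, both estimators and segmentation on each, and
scores them against the noise-free ground-truth angle. It reports the
battery-averaged per-tap ICC of AL-C and AL-R, their RMS errors, and the
absolute/relative aperture errors of AL-C:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness (session contents, sensor noise, mounting rotations) derives
from `--seed`.

## Layout

- `R/` — rotation algebra and quaternion oracle, calibration, the two angle
  estimators, segmentation, motion-capture reference, agreement metrics,
  the tapping simulator, I/O and pipeline, CLI.
- `tests/testthat/` — unit, property and acceptance suites (all fixtures are
  generated in code).
- `vignettes/tapping-angle-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and what the simulator does and does not emulate.
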