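Package: fingertap
Title: Finger-Tapping Angle Estimation from Paired Fingertip Gyroscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the clinical finger-tapping test from two fingertip-mounted
    3D gyroscopes (thumb and index finger). Implements autocalibration of the
    inter-sensor rotation while the fingers are pressed together, two tapping-angle
    estimators (a continuous rotation-matrix update and a drift-resistant resetting
    integrator), dominant-axis detection and realignment, autocorrelation-based tap
    segmentation with baseline removal, per-tap features (duration, aperture, peak
    opening and closing speed), an optical motion-capture reference path from
    3-marker rigid boards, and agreement metrics (per-tap intraclass correlation,
    RMS error, aperture errors). A rigid-body tapping simulator generates ground-truth
    sessions for eleven clinically observed tapping patterns with a configurable
    gyroscope sensor model (noise, bias walk, quantization, saturation), so the whole
    pipeline is testable without hardware or clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
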