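test_that("the ground-truth pulse train has the commanded structure", {
  # pattern 1 at 2 Hz over 15 s: exactly 30 taps
  tr <- generate_truth(pattern_spec(1), fs = 200, seed = 1)
  expect_equal(tr$tap_count, 30)
  expect_true(all(tr$theta >= -1e-12))
  closure_idx <- round(tr$tap_starts_s * 200) + 1
  expect_lt(max(abs(tr$theta[closure_idx])), 1e-9)

  # a forced single skip of one period: one tap fewer, one double-length tap
  sp <- pattern_spec(9, skip_probability = 0.04)
  found <- FALSE
  for (s in 1:50) {
    tr9 <- generate_truth(sp, fs = 200, seed = s)
    if (sum(tr9$events$type == "skip_open") == 1) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(tr9$tap_count, 2 * 15 - 1)
  durs <- tr9$tap_ends_s - tr9$tap_starts_s
  expect_equal(sum(abs(durs - 1.0) < 1e-9), 1)
  expect_equal(sum(abs(durs - 0.5) < 1e-9), tr9$tap_count - 1)

  # tremor pattern: spectral line at the tremor frequency with the set amplitude
  tr6 <- generate_truth(pattern_spec(6), fs = 200, seed = 2)
  n <- length(tr6$theta)
  sp_amp <- 2 * abs(stats::fft(tr6$theta)) / n
  freqs <- (seq_len(n) - 1) * 200 / n
  k <- which.min(abs(freqs - 5))
  expect_equal(rad2deg(max(sp_amp[(k - 2):(k + 2)])), 3, tolerance = 0.15)
})

test_that("truth orientations reproduce the commanded angle through the raw-angle map", {
  sp <- pattern_spec(1, coupling = c(0, 0))
  tr <- generate_truth(sp, fs = 200, seed = 3)
  C <- euler_to_matrix(c(0.3, -0.5, 0.7))
  # arbitrary whole-hand motion must not leak into the relative rotation
  n <- length(tr$theta)
  hand <- array(0, c(3, 3, n))
  for (i in 1:n) hand[, , i] <- euler_to_matrix(c(sin(i / 50), cos(i / 70), sin(i / 90)))
  po <- truth_to_orientations(tr$theta, sp, hand = hand, mount = C)
  a0 <- raw_angle(C)
  for (i in seq(1, n, by = 100)) {
    rel <- crossprod(po$R2[, , i], po$R1[, , i])
    expect_equal(raw_angle(rel), a0 - tr$theta[i], tolerance = 1e-9)
  }

  # zero angle, identity hand: both poses equal the mounts
  po0 <- truth_to_orientations(rep(0, 10), sp, mount = diag(3))
  expect_equal(po0$R1[, , 5], diag(3))
  expect_equal(po0$R2[, , 5], diag(3))
})

test_that("gyro extraction from poses matches closed forms", {
  dt <- 1 / 200
  n <- 400
  t <- (0:(n - 1)) * dt

  # constant rate about y
  R <- array(0, c(3, 3, n))
  for (i in 1:n) R[, , i] <- axis_rotation("y", 2 * t[i])
  w <- orientations_to_gyro(R, dt)
  expect_equal(w[20:380, ], matrix(rep(c(0, 2, 0), each = 361), 361, 3),
               tolerance = 1e-4)  # central differences: O(dt^2) amplitude factor

  # sinusoidal angle: omega = dangle/dt within 0.1% at 200 Hz
  ang <- 0.5 * sin(2 * pi * 2 * t)
  for (i in 1:n) R[, , i] <- axis_rotation("x", ang[i])
  w <- orientations_to_gyro(R, dt)
  w_true <- 0.5 * 2 * pi * 2 * cos(2 * pi * 2 * t)
  core <- 10:390
  expect_lt(max(abs(w[core, 1] - w_true[core])) / max(abs(w_true)), 0.001)

  # static pose: zero
  for (i in 1:n) R[, , i] <- euler_to_matrix(c(0.1, 0.2, 0.3))
  expect_equal(max(abs(orientations_to_gyro(R, dt))), 0)
})

test_that("the sensor model quantizes, clips and is seed-deterministic", {
  w <- matrix(seq(-2500, 2500, length.out = 300), 100, 3)
  quiet <- sensor_spec(white_noise_sigma = 0, bias_walk = 0, initial_bias = 0)
  out <- apply_sensor_model(w, quiet, seed = 1)
  step <- 2 * 2000 / 2^12
  expect_equal(quiet$quant_step, 4000 / 4096)
  inside <- abs(w) < 2000 - step
  expect_true(all(abs(out[inside] - w[inside]) <= step / 2 + 1e-12))
  expect_true(all(out[w > 2100] == 2000))
  expect_true(all(out[w < -2100] == -2000))
  expect_true(all(abs(out / step - round(out / step)) < 1e-9))

  noisy <- sensor_spec()
  a <- apply_sensor_model(w, noisy, seed = 7)
  b <- apply_sensor_model(w, noisy, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, apply_sensor_model(w, noisy, seed = 8)))
})

test_that("a default session has the protocol layout and is reproducible", {
  ses <- generate_session(pattern_spec(1), seed = 42)
  expect_equal(session_length(ses), 3500)
  expect_equal(ses$t[session_length(ses)], 17.5 - 1 / 200)
  expect_equal(ses$fs, 200)
  ses2 <- generate_session(pattern_spec(1), seed = 42)
  expect_identical(ses$w1, ses2$w1)
  expect_identical(ses$w2, ses2$w2)
  expect_identical(ses$truth$theta, ses2$truth$theta)

  # still and calibration phases have closed fingers: truth angle zero
  expect_equal(max(abs(ses$truth$theta[1:500])), 0)

  # clean end-to-end calibration recovery
  clean <- generate_session(pattern_spec(1),
                            sensor = sensor_spec(white_noise_sigma = 0, bias_walk = 0,
                                                 resolution_bits = 24),
                            seed = 43, markers = FALSE)
  win <- detect_calibration_window(clean)
  cal <- estimate_initial_rotation(clean, win)
  ang <- acos(pmin(1, (sum(diag(crossprod(clean$truth$R_true, cal$R0))) - 1) / 2))
  expect_lt(ang, 1e-3)
})

test_that("pattern-1 cross-axis energies sit in the observed regime", {
  ses <- generate_session(pattern_spec(1), seed = 44, markers = FALSE)
  win <- detect_calibration_window(ses)
  cal <- estimate_initial_rotation(ses, win)
  tr <- run_alc(ses, cal$R0, start_index = win$end)
  tap0 <- which(tr$t >= ses$truth$tapping_start_s)[1]
  e <- axis_energy(tr$wr[tap0:nrow(tr$wr), ], 1 / ses$fs)
  # x about 21% of y and z about 11% of y, within +/-50%
  expect_gt(e[["Iy"]], max(e[["Ix"]], e[["Iz"]]))
  expect_gt(e[["Ix"]] / e[["Iy"]], 0.105); expect_lt(e[["Ix"]] / e[["Iy"]], 0.315)
  expect_gt(e[["Iz"]] / e[["Iy"]], 0.055); expect_lt(e[["Iz"]] / e[["Iy"]], 0.165)
})
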