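test_that("relative angular velocity follows the rotation-then-difference rule", {
  w <- c(0.3, -0.2, 0.8)
  expect_equal(relative_angular_velocity(diag(3), w, w), c(0, 0, 0))
  expect_equal(relative_angular_velocity(axis_rotation("z", pi / 2), c(1, 0, 0), c(0, 0, 0)),
               c(0, 1, 0), tolerance = 1e-15)
  set.seed(11)
  for (i in 1:10) {
    R <- random_rotation()
    w1 <- stats::rnorm(3); w2 <- stats::rnorm(3)
    expect_equal(relative_angular_velocity(R, w1, w2),
                 c(R[1, ] %*% w1, R[2, ] %*% w1, R[3, ] %*% w1) - w2,
                 tolerance = 1e-12)
  }
  # series form matches the per-sample form
  W1 <- matrix(stats::rnorm(30), 10, 3); W2 <- matrix(stats::rnorm(30), 10, 3)
  R <- random_rotation()
  out <- relative_angular_velocity(R, W1, W2)
  expect_equal(out[4, ], relative_angular_velocity(R, W1[4, ], W2[4, ]))
})

test_that("axis energies integrate squared components (closed forms and stated ratios)", {
  n <- 2000; dt <- 1 / 200
  t <- (0:(n - 1)) * dt
  wy <- 2 * sin(2 * pi * 2 * t)
  e <- axis_energy(cbind(0, wy, 0), dt)
  expect_equal(e[["Ix"]], 0)
  expect_equal(e[["Iz"]], 0)
  # sinusoid amplitude A over duration T: energy A^2 T / 2
  expect_equal(e[["Iy"]], 2^2 * n * dt / 2, tolerance = 0.01 * 2^2 * n * dt / 2)

  # construct components with energy ratios 0.21 : 1 : 0.11
  wr <- cbind(sqrt(0.21) * 2 * sin(2 * pi * 2.6 * t), wy, sqrt(0.11) * 2 * sin(2 * pi * 3.4 * t))
  e <- axis_energy(wr, dt)
  expect_equal(e[["Ix"]] / e[["Iy"]], 0.21, tolerance = 0.01)
  expect_equal(e[["Iz"]] / e[["Iy"]], 0.11, tolerance = 0.01)
})

test_that("index-frame realignment maps the dominant axis onto y and is idempotent", {
  n <- 3000; dt <- 1 / 200
  t <- (0:(n - 1)) * dt
  s <- abs(sin(2 * pi * 2 * t)) * 3  # opening-positive rate profile

  # y already dominant: skipped
  ra <- realign_index_frame(cbind(0.1 * s, s, 0.1 * s), dt)
  expect_false(ra$applied)
  expect_equal(ra$Q, diag(3))

  # pure z rotation: z -> y
  ra <- realign_index_frame(cbind(0 * s, 0 * s, s), dt)
  expect_true(ra$applied)
  wr2 <- tcrossprod(cbind(0 * s, 0 * s, s), ra$Q)
  e2 <- axis_energy(wr2, dt)
  expect_gt(e2[["Iy"]], max(e2[["Ix"]], e2[["Iz"]]))

  # oblique axis between y and z (z-leaning, so realignment must engage)
  wr <- cbind(0 * s, s * cos(deg2rad(50)), s * sin(deg2rad(50)))
  ra <- realign_index_frame(wr, dt)
  expect_true(ra$applied)
  wr2 <- tcrossprod(wr, ra$Q)
  e2 <- axis_energy(wr2, dt)
  expect_gt(e2[["Iy"]] / sum(e2), 0.9)

  # idempotence: the realigned series needs no further realignment
  ra2 <- realign_index_frame(wr2, dt)
  expect_false(ra2$applied)

  # near-isotropic energy with y not dominant: warning and identity
  set.seed(12)
  iso <- matrix(stats::rnorm(3 * n), n, 3)
  iso[, 1] <- iso[, 1] * 1.1  # x marginally dominant, no clear axis
  expect_warning(ra3 <- realign_index_frame(iso, dt), "isotropic|dominant")
  expect_equal(ra3$Q, diag(3))
})

test_that("AL-C recovers the tapping angle on clean rigid-body sessions", {
  spec <- pattern_spec(1, coupling = c(0, 0))
  clean <- sensor_spec(white_noise_sigma = 0, bias_walk = 0, resolution_bits = 24)
  ses <- generate_session(spec, sensor = clean, seed = 21, markers = FALSE)

  # zero relative motion: constant angle
  still <- tap_session(ses$t, matrix(0, session_length(ses), 3),
                       matrix(0, session_length(ses), 3))
  tr0 <- run_alc(still, ses$truth$R_true)
  expect_lt(diff(range(tr0$alpha)), 1e-12)

  # moving hand, pure y relative rotation: theta tracks truth within 0.5 deg
  # at the estimator's effective timestamps (the causal rectangle-rule update
  # carries a half-sample time lag), and within 1 deg sampled pointwise
  win <- detect_calibration_window(ses)
  tr <- run_alc(ses, ses$truth$R_true, start_index = win$end)
  idx <- seq.int(win$end, session_length(ses))
  tt <- ses$truth$theta[idx] - ses$truth$theta[idx[1]]
  est <- tr$theta - tr$theta[1]
  expect_lt(max(abs(est - tt)) * 180 / pi, 1)
  tt_lagged <- stats::approx(tr$t, tt, xout = tr$t - 0.5 / ses$fs, rule = 2)$y
  expect_lt(max(abs(est - tt_lagged)) * 180 / pi, 0.5)

  # orthonormality preserved over the full sequence
  expect_lt(max(abs(crossprod(tr$R_final) - diag(3))), 1e-9)
})

test_that("AL-C agrees with the quaternion oracle on the same relative stream", {
  set.seed(22)
  n <- 2000; dt <- 1 / 200
  wr <- smooth_omega_stream(n, dt, rms_dps = 20)
  R0 <- random_rotation(45)
  qa <- oracle_integrate(wr, dt, R0 = R0, step = "exact")
  # feed the exact relative stream through AL-C mechanics: w1 = 0, w2 = -wr, R = R0
  ses <- tap_session((0:(n - 1)) * dt, matrix(0, n, 3), -wr)
  tr <- run_alc(ses, R0)
  a_or <- vapply(seq_len(n), function(i) raw_angle(qa[, , i]), numeric(1))
  expect_lt(max(abs(tr$alpha - a_or)) * 180 / pi, 0.1)
})

test_that("AL-R matches AL-C on pure-y tapping and beats it under saturation", {
  spec <- pattern_spec(1, coupling = c(0, 0))
  clean <- sensor_spec(white_noise_sigma = 0, bias_walk = 0, resolution_bits = 24)
  ses <- generate_session(spec, sensor = clean, seed = 23, markers = FALSE)
  win <- detect_calibration_window(ses)
  R0 <- ses$truth$R_true
  alc <- run_alc(ses, R0, start_index = win$end)
  alr <- run_alr(ses, R0, start_index = win$end)
  expect_lt(max(abs(alr$theta - alc$theta)) * 180 / pi, 0.5)

  # constant frames, zero motion: zero trace
  still <- tap_session(ses$t, matrix(0, session_length(ses), 3),
                       matrix(0, session_length(ses), 3))
  tr0 <- run_alr(still, R0)
  expect_lt(diff(range(tr0$theta)), 1e-12)

  # saturation during vigorous multi-axis movement corrupts the full matrix
  # chain (the corrupted rotation then misrotates every later sample) more
  # than the frozen-row projection; compared after baseline removal
  sp <- pattern_spec(2, tap_rate = 3.5, aperture_amp = deg2rad(70),
                     hand_motion = "slow_rotation",
                     hand_roll_amp = deg2rad(90), hand_roll_freq = 0.7)
  sat <- sensor_spec(full_scale = 500, white_noise_sigma = 0, bias_walk = 0,
                     resolution_bits = 24)
  ses2 <- generate_session(sp, sensor = sat, seed = 24, markers = FALSE,
                           mount_euler = deg2rad(c(10, 50, -10)))
  ev <- evaluate_session(ses2)
  expect_gt(ev$rmse_alc_deg, 3)  # clipping visibly corrupts the matrix chain
  expect_lt(ev$rmse_alr_deg, ev$rmse_alc_deg)
})

test_that("final drift measures accumulated bias and drives algorithm selection", {
  spec <- pattern_spec(1, coupling = c(0, 0))
  clean <- sensor_spec(white_noise_sigma = 0, bias_walk = 0, resolution_bits = 24)
  ses <- generate_session(spec, sensor = clean, seed = 25, markers = FALSE)
  win <- detect_calibration_window(ses)
  tr <- run_alc(ses, ses$truth$R_true, start_index = win$end)
  expect_lt(rad2deg(estimate_drift(tr)), 2)

  # inject a constant bias on the index y channel after calibration
  b <- deg2rad(3)
  ses_b <- ses
  idx <- seq.int(win$end, session_length(ses))
  ses_b$w2[idx, 2] <- ses_b$w2[idx, 2] + b
  tr_b <- run_alc(ses_b, ses$truth$R_true, start_index = win$end)
  T_trace <- diff(range(tr_b$t))
  expect_equal(estimate_drift(tr_b), b * T_trace, tolerance = 0.15 * b * T_trace)

  # shifting a trace by a constant leaves the drift unchanged
  tr_s <- tr_b
  tr_s$alpha <- tr_s$alpha + 0.7
  expect_equal(estimate_drift(tr_s), estimate_drift(tr_b))

  expect_equal(select_algorithm(deg2rad(70)), "AL-R")
  expect_equal(select_algorithm(deg2rad(10)), "AL-C")
  expect_equal(select_algorithm(deg2rad(60)), "AL-C")  # strict threshold
})
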