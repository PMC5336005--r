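test_that("the autocorrelation period estimate finds the tapping period", {
  dt <- 1 / 200
  t <- seq(0, 10, by = dt)
  theta <- 20 * sin(2 * pi * 2 * t)  # 2 Hz, period 0.5 s
  expect_equal(estimate_period(theta, dt), 0.5, tolerance = dt * 1.01)

  # invariance to constant offset and sign flip
  expect_equal(estimate_period(theta + 100, dt), estimate_period(theta, dt))
  expect_equal(estimate_period(-theta, dt), estimate_period(theta, dt))

  # 3 taps/s with tremor overlay from the simulator
  ses <- generate_session(pattern_spec(6, tap_rate = 3), seed = 31, markers = FALSE)
  idx <- seq.int(501, session_length(ses))
  p <- estimate_period(ses$truth$theta[idx], dt)
  expect_equal(p, 1 / 3, tolerance = 0.1 / 3)

  # white noise is aperiodic
  set.seed(32)
  expect_error(estimate_period(stats::rnorm(1000), dt), class = "fingertap_aperiodic")
})

test_that("the averaging filter is zero-phase with the closed-form gain", {
  dt <- 1 / 200; period <- 0.5
  expect_equal(smooth_theta(rep(3, 500), period, dt), rep(3, 500))

  # moving-average gain for a sinusoid: sin(pi f N dt) / (N sin(pi f dt))
  t <- seq(0, 10, by = dt)
  f <- 2
  x <- sin(2 * pi * f * t)
  y <- smooth_theta(x, period, dt)
  N <- round(period / 8 / dt)
  if (N %% 2 == 0) N <- N + 1
  gain_expected <- sin(pi * f * N * dt) / (N * sin(pi * f * dt))
  core <- 200:1800
  gain_measured <- sqrt(mean(y[core]^2) / mean(x[core]^2))
  expect_equal(gain_measured, gain_expected, tolerance = 0.01)

  # a single-sample impulse is attenuated by at least the window factor
  imp <- numeric(500); imp[250] <- 1
  expect_lte(max(smooth_theta(imp, period, dt)), 1 / N + 1e-12)
})

test_that("tap boundaries match the generator's truth, including skip patterns", {
  cfg <- default_config()$segmentation
  run_seg <- function(ses) {
    idx <- seq.int(1L, session_length(ses))
    theta <- ses$truth$theta
    p <- estimate_period(theta[501:length(theta)], 1 / ses$fs)
    find_tap_boundaries(theta, p, 1 / ses$fs)
  }
  ses1 <- generate_session(pattern_spec(1), seed = 33, markers = FALSE)
  ts1 <- run_seg(ses1)
  expect_equal(ts1$n_taps, ses1$truth$tap_count)
  expect_true(all(diff(ts1$boundaries) > 0))
  expect_true(all(ts1$maxima > ts1$boundaries[-length(ts1$boundaries)] &
                    ts1$maxima < ts1$boundaries[-1]))

  # pattern 9 skips a tap while open: the prolonged tap counts once
  ses9 <- generate_session(pattern_spec(9), seed = 20, markers = FALSE)
  expect_gt(nrow(ses9$truth$events[ses9$truth$events$type == "skip_open", ]), 0)
  ts9 <- run_seg(ses9)
  expect_equal(ts9$n_taps, ses9$truth$tap_count)

  # constant signal has no taps (period from a separate periodic signal)
  expect_error(find_tap_boundaries(rep(1, 1000), 0.5, 1 / 200),
               class = "fingertap_no_taps")
})

test_that("baseline removal zeroes every boundary and undoes a linear ramp", {
  ses <- generate_session(pattern_spec(1, coupling = c(0, 0)),
                          sensor = sensor_spec(white_noise_sigma = 0, bias_walk = 0,
                                               resolution_bits = 24),
                          seed = 34, markers = FALSE)
  theta <- ses$truth$theta
  dt <- 1 / ses$fs
  p <- estimate_period(theta[501:length(theta)], dt)
  ts <- find_tap_boundaries(theta, p, dt)

  ramp <- seq(0, deg2rad(20), length.out = length(theta))
  drifted <- theta + ramp
  ts_d <- find_tap_boundaries(drifted, p, dt)
  rec <- remove_baseline(drifted, ts_d)
  expect_equal(rec[ts_d$boundaries], rep(0, length(ts_d$boundaries)))
  interior <- seq.int(ts_d$boundaries[2], ts_d$boundaries[ts_d$n_taps])
  expect_lt(max(abs(rec[interior] - theta[interior])) * 180 / pi, 0.5)

  # single-boundary set removes a constant offset
  one <- structure(list(boundaries = 10L, maxima = integer(0), n_taps = 0L,
                        period = p, dt = dt, features = NULL), class = "tap_set")
  expect_equal(remove_baseline(theta + 1, one), theta + 1 - (theta + 1)[10])
})

test_that("per-tap features recover amplitude, duration and telescoping spans", {
  # synthetic raised-cosine train: A = 40 deg, period 0.5 s
  dt <- 1 / 200
  t <- seq(0, 10 - dt, by = dt)
  A <- deg2rad(40)
  theta <- A / 2 * (1 - cos(2 * pi * 2 * t))
  ts <- find_tap_boundaries(theta, 0.5, dt)
  ts <- extract_tap_features(theta, ts, dt)
  f <- ts$features
  expect_true(all(abs(rad2deg(f$aperture) - 40) < 1))
  expect_true(all(abs(f$duration_s - 0.5) <= dt + 1e-12))
  expect_equal(sum(f$duration_s),
               (ts$boundaries[length(ts$boundaries)] - ts$boundaries[1]) * dt)

  # peak speeds: max |dtheta/dt| = A * pi * rate for the raised cosine
  expect_equal(max(f$peak_opening_speed), A * pi * 2, tolerance = 0.02 * A * pi * 2)
  expect_equal(min(f$peak_closing_speed), -A * pi * 2, tolerance = 0.02 * A * pi * 2)

  # zero-amplitude degenerate tap
  flat <- structure(list(boundaries = c(1L, 50L, 100L), maxima = c(25L, 75L),
                         n_taps = 2L, period = 0.25, dt = dt, features = NULL),
                    class = "tap_set")
  ff <- extract_tap_features(rep(0, 100), flat, dt)
  expect_equal(ff$features$aperture, c(0, 0))
})
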