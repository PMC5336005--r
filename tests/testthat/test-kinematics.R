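test_that("axis rotations have the standard right-handed form and compose to identity", {
  expect_equal(axis_rotation("y", pi / 2),
               matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3),
               tolerance = 1e-15)
  expect_equal(axis_rotation("x", 0), diag(3))
  expect_equal(axis_rotation("z", 0.3) %*% axis_rotation("z", -0.3), diag(3),
               tolerance = 1e-12)
  expect_error(axis_rotation("w", 1), "axis")
})

test_that("euler_to_matrix is the ordered z-y-x product and round-trips", {
  expect_equal(euler_to_matrix(c(0, 0, 0)), diag(3))
  expect_equal(euler_to_matrix(c(pi / 2, 0, 0)), axis_rotation("x", pi / 2))

  # independent oracle: direct three-matrix product typed out
  e <- c(10, 20, 30) * pi / 180
  cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
  cz <- cos(e[3]); sz <- sin(e[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  expect_equal(euler_to_matrix(e), Rz %*% Ry %*% Rx, tolerance = 1e-14)

  # round-trip away from gimbal lock
  set.seed(41)
  for (i in 1:50) {
    e <- c(stats::runif(1, -pi, pi), stats::runif(1, -(pi / 2 - 0.1), pi / 2 - 0.1),
           stats::runif(1, -pi, pi))
    expect_equal(matrix_to_euler(euler_to_matrix(e)), e, tolerance = 1e-9)
  }
})

test_that("small_angle_update uses exact trig, preserves orthonormality, and integrates a pure y rotation", {
  R <- euler_to_matrix(c(0.2, -0.4, 1.1))
  expect_equal(small_angle_update(R, c(0, 0, 0)), R)

  # 1000 steps of dphi_y = 1/1000 from identity: raw angle must be -1 rad
  Rn <- diag(3)
  for (i in 1:1000) Rn <- small_angle_update(Rn, c(0, 1 / 1000, 0))
  expect_equal(raw_angle(Rn), -1, tolerance = 1e-9)
  expect_equal(Rn, axis_rotation("y", 1), tolerance = 1e-9)

  set.seed(42)
  Rn <- random_rotation()
  for (i in 1:200) Rn <- small_angle_update(Rn, stats::rnorm(3, 0, 0.02))
  expect_lt(max(abs(crossprod(Rn) - diag(3))), 1e-12)
})

test_that("raw_angle matches the geometric projection oracle and flags the degenerate case", {
  expect_equal(raw_angle(diag(3)), 0)
  for (b in seq(-3, 3, by = 0.25)) {
    expect_equal(raw_angle(axis_rotation("y", b)), -b, tolerance = 1e-12)
  }
  set.seed(43)
  for (i in 1:50) {
    R <- random_rotation()
    if (R[3, 1]^2 + R[1, 1]^2 < 1e-6) next
    expect_equal(raw_angle(R), raw_angle_oracle(R), tolerance = 1e-10)
  }
  # x1 parallel to y2: projection undefined
  expect_error(raw_angle(axis_rotation("z", pi / 2)),
               class = "fingertap_undefined_angle")
})

test_that("quaternion oracle reproduces closed forms and mirrors the matrix chain", {
  n <- 400; dt <- 1 / 200
  expect_equal(oracle_integrate(matrix(0, n, 3), dt)[, , n], diag(3))

  # constant rate about y: closed form
  w <- matrix(rep(c(0, 2, 0), each = n), n, 3)
  out <- oracle_integrate(w, dt, step = "exact")
  expect_equal(out[, , n], axis_rotation("y", 2 * (n - 1) * dt), tolerance = 1e-8)

  # euler-split quaternion mirror vs the matrix chain: same map, independent
  # algebra, so agreement is round-off even for strong multi-axis streams
  set.seed(44)
  w <- smooth_omega_stream(3000, dt, rms_dps = 300)
  w <- w * (10 / max(sqrt(rowSums(w^2))))  # scale to peak 10 rad/s
  qa <- oracle_integrate(w, dt, step = "euler")
  R <- diag(3)
  worst <- 0
  for (i in seq_len(nrow(w))) {
    worst <- max(worst, sqrt(sum((R - qa[, , i])^2)))
    R <- small_angle_update(R, w[i, ] * dt)
  }
  expect_lt(worst, 1e-4)
})

test_that("exact-exponential oracle discrepancy shrinks quadratically with the step", {
  set.seed(45)
  t_end <- 4; f <- 1.3
  disc <- sapply(c(1, 2, 4), function(refine) {
    dt <- (1 / 200) / refine
    t <- seq(0, t_end, by = dt)
    w <- cbind(1.5 * sin(2 * pi * f * t), 2.0 * cos(2 * pi * 0.7 * t),
               1.0 * sin(2 * pi * 1.1 * t + 0.5))
    qa <- oracle_integrate(w, dt, step = "exact")
    R <- diag(3)
    for (i in seq_len(nrow(w) - 1)) R <- small_angle_update(R, w[i, ] * dt)
    sqrt(sum((R - qa[, , nrow(w)])^2))
  })
  # per-step commutator defect is O(dt^2) over O(1/dt) steps: total O(dt),
  # so halving the step should halve the discrepancy
  expect_lt(disc[2], disc[1] / 1.7)
  expect_lt(disc[3], disc[2] / 1.7)
})
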