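# Shared fixture builders. All fixtures are generated in code; seeds fixed.

deg <- function(x) x * pi / 180

# random proper rotation from uniform Euler draws (bounded per axis)
random_rotation <- function(max_deg = 180) {
  euler_to_matrix(stats::runif(3, -deg(max_deg), deg(max_deg)))
}

# smooth multi-sine angular-velocity stream, n x 3 (rad/s)
smooth_omega_stream <- function(n, dt, rms_dps = 20, fmax = 2, axes = 1:3) {
  t <- (seq_len(n) - 1) * dt
  w <- matrix(0, n, 3)
  for (j in axes) {
    x <- numeric(n)
    for (k in 1:3) {
      f <- stats::runif(1, 0.2, fmax)
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + sin(2 * pi * f * t + ph)
    }
    w[, j] <- deg2rad(rms_dps) * x / sqrt(mean(x^2))
  }
  w
}

# minimal co-moving session: both sensors see the same rotation through R_true,
# active only on sample range `active`, magnitudes well above the vigor level
comoving_session <- function(n = 1000, active = 100:499, R_true = diag(3),
                             fs = 200, noise_dps = 0) {
  t <- (seq_len(n) - 1) / fs
  w1 <- matrix(0, n, 3)
  ta <- t[active] - t[active[1]]
  # constant-magnitude rotating angular velocity: excites all axes
  mag <- deg2rad(120)
  w1[active, ] <- mag * cbind(sin(2 * pi * 1.1 * ta), cos(2 * pi * 1.1 * ta),
                              sin(2 * pi * 0.7 * ta + 1))
  w2 <- tcrossprod(w1, R_true)
  if (noise_dps > 0) {
    w1 <- w1 + matrix(stats::rnorm(3 * n, 0, deg2rad(noise_dps)), n, 3)
    w2 <- w2 + matrix(stats::rnorm(3 * n, 0, deg2rad(noise_dps)), n, 3)
  }
  tap_session(t, w1, w2)
}

# independent ANOVA-based ICC(A,1) oracle via stats::aov mean squares
icc_a1_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(
    value = c(x, y),
    target = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(value ~ target + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# geometric raw-angle oracle: signed angle between the projection of the
# thumb x1 axis onto the index x2-z2 plane and the x2 axis (right-hand about y2)
raw_angle_oracle <- function(R) {
  x1 <- R[, 1]                     # x1 axis in index components
  p <- c(x1[1], 0, x1[3])          # projection onto the x-z plane
  p <- p / sqrt(sum(p^2))
  ang <- acos(max(-1, min(1, p[1])))
  # sign: positive alpha rotates x2 toward +z2 direction per right-hand rule
  if (p[3] < 0) ang <- -ang
  ang
}
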