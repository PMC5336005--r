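#' Elementary axis rotation matrix
#'
#' Right-handed rotation of coordinates about one Cartesian axis. `axis_rotation("y", b)`
#' rotates a vector's components by `b` radians about the y axis, i.e. the standard form
#' with `cos(b)` on the diagonal and `sin(b)` in the (1,3) entry.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle Rotation angle in radians (finite scalar).
#' @return A 3x3 orthonormal rotation matrix.
#' @export
#' @examples
#' axis_rotation("y", pi / 2)
axis_rotation <- function(axis, angle) {
  if (!is.character(axis) || length(axis) != 1L || !axis %in% c("x", "y", "z")) {
    stop("`axis` must be one of \"x\", \"y\", \"z\"", call. = FALSE)
  }
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  c_ <- cos(angle)
  s_ <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Rotation matrix from x-y-z Euler angles
#'
#' Composes three subsequent rotations about the fixed axes of the target frame,
#' `R = Rz(phi_z) %*% Ry(phi_y) %*% Rx(phi_x)`. The product of orthonormal factors
#' is orthonormal by construction, which is why the calibration optimises over
#' these three angles rather than over nine matrix entries.
#'
#' @param euler Numeric length-3 vector `c(phi_x, phi_y, phi_z)` in radians.
#' @return A 3x3 rotation matrix.
#' @seealso [matrix_to_euler()] for the inverse away from gimbal lock.
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(is.numeric(euler), length(euler) == 3L, all(is.finite(euler)))
  axis_rotation("z", euler[3L]) %*% axis_rotation("y", euler[2L]) %*% axis_rotation("x", euler[1L])
}

#' Euler angles from a rotation matrix
#'
#' Inverts [euler_to_matrix()]. Well-conditioned away from gimbal lock
#' (`|phi_y|` near `pi/2`).
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric length-3 vector `c(phi_x, phi_y, phi_z)` in radians, each in `(-pi, pi]`.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  phi_y <- asin(max(-1, min(1, -R[3L, 1L])))
  phi_x <- atan2(R[3L, 2L], R[3L, 3L])
  phi_z <- atan2(R[2L, 1L], R[1L, 1L])
  c(phi_x, phi_y, phi_z)
}

#' Check that a matrix is a proper rotation
#'
#' @param R A 3x3 matrix.
#' @param tol Elementwise tolerance on `t(R) %*% R - I` and on `det(R) - 1`.
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' Re-orthonormalize a nearly-orthonormal matrix
#'
#' Gram-Schmidt on the columns; a guard against round-off accumulation in very
#' long update chains. Not needed in normal operation (the product of exact
#' rotation factors stays orthonormal to round-off).
#'
#' @param R A 3x3 matrix close to a rotation.
#' @return A 3x3 orthonormal matrix.
#' @export
orthonormalize <- function(R) {
  x <- R[, 1L] / sqrt(sum(R[, 1L]^2))
  y <- R[, 2L] - sum(R[, 2L] * x) * x
  y <- y / sqrt(sum(y^2))
  z <- c(
    x[2L] * y[3L] - x[3L] * y[2L],
    x[3L] * y[1L] - x[1L] * y[3L],
    x[1L] * y[2L] - x[2L] * y[1L]
  )
  cbind(x, y, z, deparse.level = 0L)
}

#' One small-rotation update step
#'
#' Updates the thumb-to-index rotation matrix for the next time step,
#' `R[n+1] = Rz(dphi_z) %*% Ry(dphi_y) %*% Rx(dphi_x) %*% R[n]`, where the
#' increments are the components of the relative angular velocity times the
#' sampling step. Exact trigonometric factors are used (not a first-order
#' linearization), so each factor is itself orthonormal.
#'
#' @param R Current 3x3 rotation matrix.
#' @param dphi Numeric length-3 vector `c(dphi_x, dphi_y, dphi_z)` in radians.
#' @return The updated 3x3 rotation matrix.
#' @export
small_angle_update <- function(R, dphi) {
  stopifnot(is.numeric(dphi), length(dphi) == 3L)
  cx <- cos(dphi[1L]); sx <- sin(dphi[1L])
  cy <- cos(dphi[2L]); sy <- sin(dphi[2L])
  cz <- cos(dphi[3L]); sz <- sin(dphi[3L])
  # Rz %*% Ry %*% Rx assembled in closed form
  dR <- matrix(c(
    cz * cy, sz * cy, -sy,
    cz * sy * sx - sz * cx, sz * sy * sx + cz * cx, cy * sx,
    cz * sy * cx + sz * sx, sz * sy * cx - cz * sx, cy * cx
  ), 3L, 3L)
  dR %*% R
}

#' Raw tapping angle from a relative rotation matrix
#'
#' Projects the thumb's longitudinal (x1) axis onto the index finger's x2-z2
#' plane and returns the signed angle between that projection and the x2 axis,
#' `alpha = atan2(r31, r11)`, positive per the right-hand rule about y2. The
#' clinical tapping angle is `theta = -alpha` (up to baseline).
#'
#' @param R 3x3 rotation matrix mapping thumb-frame components into the index frame.
#' @return Angle in radians, in `(-pi, pi]`.
#' @export
raw_angle <- function(R) {
  r31 <- R[3L, 1L]
  r11 <- R[1L, 1L]
  if (r31^2 + r11^2 < 1e-12) {
    stop(undefined_angle_error())
  }
  atan2(r31, r11)
}

undefined_angle_error <- function() {
  structure(
    class = c("fingertap_undefined_angle", "fingertap_error", "error", "condition"),
    list(message = "tapping angle undefined: thumb x1-axis is parallel to the index y2-axis", call = NULL)
  )
}

## ---- quaternion oracle -----------------------------------------------------

quat_mult <- function(p, q) {
  c(
    p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L]
  )
}

quat_from_axis_angle <- function(axis_unit, angle) {
  c(cos(angle / 2), sin(angle / 2) * axis_unit)
}

quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L)
}

quat_exp_step <- function(v) {
  a <- sqrt(sum(v^2))
  if (a < 1e-300) return(c(1, 0, 0, 0))
  quat_from_axis_angle(v / a, a)
}

#' Quaternion integration oracle for a relative angular-velocity stream
#'
#' Integrates the same premultiplicative (space-frame, index-finger) angular
#' velocity used by the continuous algorithm, but in quaternion algebra, with
#' renormalization at every step. Used as an independent test oracle for the
#' rotation-matrix chain.
#'
#' Two step conventions are available. `"exact"` applies the quaternion
#' exponential of the full rotation vector `omega * dt` per step -- a genuinely
#' different integrator that agrees with the matrix chain to second order.
#' `"euler"` composes the same ordered z-y-x split as the matrix update, in
#' quaternion form -- algebraically the same map through an independent algebra,
#' so agreement is limited only by round-off.
#'
#' @param omega_rel Numeric n x 3 matrix of relative angular velocity (rad/s),
#'   index-frame components.
#' @param dt Sampling step in seconds.
#' @param R0 Initial rotation matrix (default identity).
#' @param step `"exact"` or `"euler"` (see Details).
#' @return A 3 x 3 x n array of rotation matrices; slice `i` corresponds to the
#'   state before applying sample `i`'s increment (matching the matrix chain).
#' @export
oracle_integrate <- function(omega_rel, dt, R0 = diag(3), step = c("exact", "euler")) {
  step <- match.arg(step)
  stopifnot(is.matrix(omega_rel), ncol(omega_rel) == 3L, dt > 0)
  n <- nrow(omega_rel)
  out <- array(NA_real_, c(3L, 3L, n))
  # initial orientation as a quaternion (rotation matrix -> quaternion, stable branch)
  q <- matrix_to_quat(R0)
  for (i in seq_len(n)) {
    out[, , i] <- quat_to_matrix(q)
    v <- omega_rel[i, ] * dt
    dq <- if (step == "exact") {
      quat_exp_step(v)
    } else {
      quat_mult(
        quat_from_axis_angle(c(0, 0, 1), v[3L]),
        quat_mult(quat_from_axis_angle(c(0, 1, 0), v[2L]), quat_from_axis_angle(c(1, 0, 0), v[1L]))
      )
    }
    q <- quat_mult(dq, q)
    q <- q / sqrt(sum(q^2))
  }
  out
}

matrix_to_quat <- function(R) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3L, 2L] - R[2L, 3L]) / s, (R[1L, 3L] - R[3L, 1L]) / s, (R[2L, 1L] - R[1L, 2L]) / s)
  } else {
    i <- which.max(c(R[1L, 1L], R[2L, 2L], R[3L, 3L]))
    if (i == 1L) {
      s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
      q <- c((R[3L, 2L] - R[2L, 3L]) / s, 0.25 * s, (R[1L, 2L] + R[2L, 1L]) / s, (R[1L, 3L] + R[3L, 1L]) / s)
    } else if (i == 2L) {
      s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
      q <- c((R[1L, 3L] - R[3L, 1L]) / s, (R[1L, 2L] + R[2L, 1L]) / s, 0.25 * s, (R[2L, 3L] + R[3L, 2L]) / s)
    } else {
      s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
      q <- c((R[2L, 1L] - R[1L, 2L]) / s, (R[1L, 3L] + R[3L, 1L]) / s, (R[2L, 3L] + R[3L, 2L]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' @noRd
deg2rad <- function(x) x * pi / 180
#' @noRd
rad2deg <- function(x) x * 180 / pi
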