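#' Relative angular velocity in the index-finger frame
#'
#' `omega_r = R %*% omega1 - omega2`: the thumb's angular velocity mapped into
#' the index frame, minus the index finger's own angular velocity. Whole-hand
#' motion cancels in this difference, which is what makes the tapping angle
#' independent of arm movement.
#'
#' @param R 3x3 rotation mapping thumb-frame components into the index frame.
#' @param w1,w2 Either length-3 vectors (one sample) or n x 3 matrices (series),
#'   rad/s.
#' @return Same shape as the inputs, rad/s, index-frame components.
#' @export
relative_angular_velocity <- function(R, w1, w2) {
  if (is.matrix(w1)) {
    tcrossprod(w1, R) - w2
  } else {
    as.numeric(R %*% w1) - w2
  }
}

#' Per-axis energy of a relative angular-velocity series
#'
#' Rectangle-rule time integrals of the squared components. The axis carrying
#' the largest integral is the dominant rotation axis; in typical tapping the
#' y2 (transversal) axis dominates.
#'
#' @param wr n x 3 matrix of relative angular velocity, rad/s.
#' @param dt Sampling step, seconds.
#' @return Named numeric vector `c(Ix, Iy, Iz)` in (rad/s)^2 * s.
#' @export
axis_energy <- function(wr, dt) {
  e <- colSums(wr * wr) * dt
  names(e) <- c("Ix", "Iy", "Iz")
  e
}

#' Rotation aligning the dominant rotation axis with y2
#'
#' When the y2 integral of the squared relative angular velocity is not
#' dominant, the index-finger coordinate system is computationally rotated so
#' that the new y2 axis points along the dominant rotation axis. The dominant
#' axis is taken as the principal eigenvector of the second-moment matrix
#' `sum(wr wr' dt)`; its sign is chosen so that the accumulated rotation about
#' it is predominantly positive (fingers opening count as positive angle), and
#' the realignment is the minimal (shortest-geodesic) rotation mapping that
#' axis onto y2.
#'
#' @param wr n x 3 matrix of relative angular velocity (index frame), rad/s.
#' @param dt Sampling step, seconds.
#' @param dominance_min Minimum fraction of total energy the principal axis
#'   must carry; below it the energy is deemed isotropic and the identity is
#'   returned with a warning.
#' @return A list with `Q` (3x3 rotation to premultiply index-frame
#'   quantities), `applied` (logical), `axis` (dominant unit axis, original
#'   index frame) and `energy` (the [axis_energy()] of the input).
#' @export
realign_index_frame <- function(wr, dt, dominance_min = 0.4) {
  e <- axis_energy(wr, dt)
  out <- list(Q = diag(3), applied = FALSE, axis = c(0, 1, 0), energy = e)
  if (e[["Iy"]] >= max(e[["Ix"]], e[["Iz"]])) {
    return(out)  # y already dominant: operation skipped
  }
  M <- crossprod(wr) * dt
  eg <- eigen(M, symmetric = TRUE)
  lam <- eg$values
  if (lam[1L] < dominance_min * sum(lam)) {
    warning("no dominant rotation axis (near-isotropic energy); keeping the original frame",
            call. = FALSE)
    return(out)
  }
  d <- eg$vectors[, 1L]
  # orient the axis so that net accumulated rotation about it is positive
  z <- cumsum(as.numeric(wr %*% d)) * dt
  if (abs(min(z)) > abs(max(z))) d <- -d
  out$axis <- d
  out$Q <- rotation_between(d, c(0, 1, 0))
  out$applied <- TRUE
  out
}

# minimal rotation Q with Q %*% a = b (unit vectors)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  c_ <- sum(a * b)
  s_ <- sqrt(sum(v^2))
  if (s_ < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2L] * p[3L] - a[3L] * p[2L],
           a[3L] * p[1L] - a[1L] * p[3L],
           a[1L] * p[2L] - a[2L] * p[1L])
    v <- v / sqrt(sum(v^2))
    K <- skew(v)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew(v / s_)
  ang <- atan2(s_, c_)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

skew <- function(v) {
  matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
}

new_tap_trace <- function(t, alpha, algorithm, fs, start_index) {
  structure(
    list(t = t, alpha = alpha, theta = -alpha, algorithm = algorithm,
         fs = fs, start_index = start_index,
         final_drift = abs(alpha[length(alpha)] - alpha[1L])),
    class = "tap_trace"
  )
}

#' @export
print.tap_trace <- function(x, ...) {
  cat(sprintf(
    "<tap_trace> %s: %d samples [%.2f, %.2f] s, theta range [%.1f, %.1f] deg, final drift %.1f deg\n",
    x$algorithm, length(x$t), x$t[1L], x$t[length(x$t)],
    rad2deg(min(x$theta)), rad2deg(max(x$theta)), rad2deg(x$final_drift)
  ))
  invisible(x)
}

#' Continuous tapping-angle algorithm (AL-C)
#'
#' Time-steps the full thumb-to-index rotation matrix: at each sample the
#' relative angular velocity is computed with the current matrix, the matrix is
#' updated through the exact small-rotation factors, and the raw angle `alpha`
#' is extracted by `atan2(r31, r11)`. The trace runs from `start_index`
#' (normally the end of the calibration window, where the fingers are still
#' pressed together) to the end of the session.
#'
#' @param session A [tap_session()].
#' @param R0 Initial rotation matrix from calibration.
#' @param start_index First sample of the trace (default 1).
#' @param end_index Last sample of the trace (default session end).
#' @param reorthonormalize_every Re-orthonormalize the running matrix every
#'   this many steps (round-off guard); 0 disables.
#' @return A `tap_trace` with `alpha`, `theta = -alpha`, the relative
#'   angular-velocity series `wr` (n x 3) and the final rotation matrix
#'   `R_final`.
#' @export
run_alc <- function(session, R0, start_index = 1L,
                    end_index = session_length(session),
                    reorthonormalize_every = 0L) {
  idx <- seq.int(start_index, end_index)
  n <- length(idx)
  dt <- session$dt
  w1 <- session$w1[idx, , drop = FALSE]
  w2 <- session$w2[idx, , drop = FALSE]
  alpha <- numeric(n)
  wr <- matrix(0, n, 3L)
  R <- R0
  for (i in seq_len(n)) {
    r31 <- R[3L, 1L]; r11 <- R[1L, 1L]
    if (r31^2 + r11^2 < 1e-12) stop(undefined_angle_error())
    alpha[i] <- atan2(r31, r11)
    w <- as.numeric(R %*% w1[i, ]) - w2[i, ]
    wr[i, ] <- w
    R <- small_angle_update(R, w * dt)
    if (reorthonormalize_every > 0L && i %% reorthonormalize_every == 0L) {
      R <- orthonormalize(R)
    }
  }
  tr <- new_tap_trace(session$t[idx], alpha, "AL-C", session$fs, start_index)
  tr$wr <- wr
  tr$R_final <- R
  tr
}

#' Resetting tapping-angle algorithm (AL-R)
#'
#' Drift-resistant approximation: the second row of the calibration rotation
#' matrix is frozen, the y2 component of the relative angular velocity is
#' `wry = r21_0 w1x + r22_0 w1y + r23_0 w1z - w2y`, and the raw angle is its
#' negative rectangle-rule integral (the rotation matrix is effectively reset
#' to its initial value at every step). The result tracks rotation about y2
#' only; residual drift is removed later with the baseline.
#'
#' @inheritParams run_alc
#' @return A `tap_trace` (alpha anchored at `raw_angle(R0)` so AL-C and AL-R
#'   traces are directly comparable before baseline removal).
#' @export
run_alr <- function(session, R0, start_index = 1L,
                    end_index = session_length(session)) {
  idx <- seq.int(start_index, end_index)
  row2 <- R0[2L, ]
  wry <- as.numeric(session$w1[idx, , drop = FALSE] %*% row2) - session$w2[idx, 2L]
  # alpha decreases as the fingers open: d(alpha)/dt = -wry
  alpha <- raw_angle(R0) - cumsum(c(0, wry[-length(wry)])) * session$dt
  new_tap_trace(session$t[idx], alpha, "AL-R", session$fs, start_index)
}

#' Final drift of an angle trace
#'
#' Absolute difference between the raw angle at the end of the sequence and at
#' the start of the trace. Both instants have the fingers closed (the sequence
#' protocol begins and ends with closed fingers and the trace starts while the
#' fingers are still pressed together after calibration), so the true
#' difference is near zero and the residual measures accumulated drift.
#'
#' @param trace A `tap_trace` covering the full tapping segment.
#' @return Drift in radians.
#' @export
estimate_drift <- function(trace) {
  abs(trace$alpha[length(trace$alpha)] - trace$alpha[1L])
}

#' Drift-based algorithm selection
#'
#' The continuous algorithm is preferred; when its final drift exceeds 60
#' degrees the resetting algorithm is automatically selected as the more
#' accurate one.
#'
#' @param drift_alc Final AL-C drift, radians.
#' @param threshold Selection threshold, radians (default 60 degrees).
#' @return `"AL-R"` if `drift_alc > threshold` (strictly), else `"AL-C"`.
#' @export
select_algorithm <- function(drift_alc, threshold = deg2rad(60)) {
  if (drift_alc > threshold) "AL-R" else "AL-C"
}
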