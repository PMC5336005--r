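#' Detect the autocalibration window
#'
#' During the calibration manoeuvre the fingers are pressed together and the
#' whole hand draws circles, so both sensors register vigorous movement while
#' their angular-velocity magnitudes stay practically equal. The detector finds
#' the earliest contiguous run of samples, within the first part of the
#' recording, where both smoothed magnitudes exceed the vigor threshold and
#' their relative mismatch stays below the mismatch threshold for at least the
#' minimum duration.
#'
#' @param session A [tap_session()].
#' @param vigor_dps Vigor threshold on both magnitudes, deg/s.
#' @param mismatch Maximum relative magnitude mismatch
#'   `|mag1 - mag2| / max(mag1, mag2)`.
#' @param min_duration_s Minimum qualifying run length, seconds.
#' @param smooth_s Moving-average width applied to the magnitudes before
#'   thresholding, seconds.
#' @param search_fraction Fraction of the recording, from the start, searched
#'   for the window (the manoeuvre precedes tapping).
#' @return A list with `start`, `end` (1-based inclusive sample indices),
#'   `t_start`, `t_end` (seconds) and `duration_s`, class `tap_window`.
#' @export
detect_calibration_window <- function(session, vigor_dps = 30, mismatch = 0.1,
                                      min_duration_s = 0.5, smooth_s = 0.05,
                                      search_fraction = 0.5) {
  n <- session_length(session)
  w <- max(1L, as.integer(round(smooth_s * session$fs)))
  mag1 <- moving_average(sqrt(rowSums(session$w1^2)), w)
  mag2 <- moving_average(sqrt(rowSums(session$w2^2)), w)
  vigor <- deg2rad(vigor_dps)
  hi <- pmax(mag1, mag2)
  ok <- mag1 > vigor & mag2 > vigor & abs(mag1 - mag2) < mismatch * hi
  limit <- max(2L, as.integer(floor(search_fraction * n)))
  ok[seq.int(limit + 1L, n)] <- FALSE
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  min_len <- as.integer(round(min_duration_s * session$fs))
  hit <- which(runs$values & runs$lengths >= min_len)
  if (!length(hit)) {
    stop(calibration_not_found_error())
  }
  k <- hit[1L]
  structure(
    list(start = starts[k], end = ends[k],
         t_start = session$t[starts[k]], t_end = session$t[ends[k]],
         duration_s = (ends[k] - starts[k] + 1L) / session$fs),
    class = "tap_window"
  )
}

calibration_not_found_error <- function() {
  structure(
    class = c("fingertap_calibration_not_found", "fingertap_error", "error", "condition"),
    list(message = paste(
      "no autocalibration window found: need a segment where both sensors move",
      "vigorously with practically equal angular-velocity magnitudes"
    ), call = NULL)
  )
}

moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Calibration cost function
#'
#' Sum over the window samples of the three squared residuals between the
#' index-sensor angular velocity and the rotated thumb-sensor angular velocity,
#' with the rotation parameterized by x-y-z Euler angles. Zero iff the rotated
#' thumb signal reproduces the index signal exactly.
#'
#' @param euler Numeric length-3 Euler angles (radians).
#' @param w1,w2 n x 3 angular-velocity matrices (rad/s), equal length.
#' @return Non-negative cost in (rad/s)^2.
#' @export
calibration_cost <- function(euler, w1, w2) {
  w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  if (nrow(w1) != nrow(w2)) stop("w1 and w2 must have equal length", call. = FALSE)
  R <- euler_to_matrix(euler)
  res <- w2 - tcrossprod(w1, R)  # w1 %*% t(R): rows are (R %*% w1_i)'
  sum(res * res)
}

#' Estimate the initial thumb-to-index rotation
#'
#' Minimizes [calibration_cost()] over the Euler angles with Nelder-Mead
#' simplex. The search starts at the origin; when the relative residual stays
#' above a small floor, six deterministic restarts from single-axis
#' `+/-restart_deg` guesses guard against local minima. The resulting rotation
#' matrix is the initial value for all subsequent angle computations.
#'
#' A low-excitation flag is raised when the calibration movement does not
#' excite all three axes (smallest-to-largest eigenvalue ratio of the
#' angular-velocity second-moment matrix below `low_excitation_ratio`): the
#' residual can then be small while the rotation component about the single
#' excited axis is unidentifiable.
#'
#' @param session A [tap_session()].
#' @param window A `tap_window` from [detect_calibration_window()].
#' @param cost_tol Relative convergence tolerance on the cost.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param restart_deg Magnitude of the single-axis restart guesses, degrees.
#' @param restart_rel_cost Relative-residual threshold above which restarts run.
#' @param low_excitation_ratio Eigenvalue-ratio threshold for the excitation flag.
#' @return A list of class `tap_calibration` with `euler` (radians), `R0`,
#'   `residual_cost`, `window`, `converged`, `low_excitation`.
#' @export
estimate_initial_rotation <- function(session, window,
                                      cost_tol = 1e-10, maxit = 5000,
                                      restart_deg = 45,
                                      restart_rel_cost = 1e-6,
                                      low_excitation_ratio = 0.01) {
  idx <- seq.int(window$start, window$end)
  w1 <- session$w1[idx, , drop = FALSE]
  w2 <- session$w2[idx, , drop = FALSE]
  scale <- sum(w2 * w2)
  if (scale <= 0) scale <- 1

  fits <- list()
  run_start <- function(par) {
    stats::optim(par, calibration_cost, w1 = w1, w2 = w2, method = "Nelder-Mead",
                 control = list(reltol = cost_tol, maxit = maxit))
  }
  fits[[1L]] <- run_start(c(0, 0, 0))
  if (fits[[1L]]$value / scale > restart_rel_cost) {
    a <- deg2rad(restart_deg)
    starts <- list(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
    for (s in starts) fits[[length(fits) + 1L]] <- run_start(s)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]

  # excitation check: second moment of the (shared) rotation seen by both sensors
  M <- (crossprod(w1) + crossprod(w2)) / (2 * nrow(w1))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  low_exc <- ev[3L] < low_excitation_ratio * ev[1L]
  if (low_exc) {
    warning("calibration movement poorly excites all three axes; ",
            "the rotation component about the dominant axis may be unidentifiable",
            call. = FALSE)
  }

  euler <- wrap_angle(best$par)
  structure(
    list(euler = euler, R0 = euler_to_matrix(euler),
         residual_cost = best$value, window = window,
         converged = best$convergence == 0L,
         low_excitation = low_exc),
    class = "tap_calibration"
  )
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' @export
print.tap_calibration <- function(x, ...) {
  cat(sprintf(
    "<tap_calibration> euler = (%.2f, %.2f, %.2f) deg, residual = %.3g (rad/s)^2, window [%.2f, %.2f] s%s%s\n",
    rad2deg(x$euler[1L]), rad2deg(x$euler[2L]), rad2deg(x$euler[3L]),
    x$residual_cost, x$window$t_start, x$window$t_end,
    if (x$converged) "" else " [NOT CONVERGED]",
    if (x$low_excitation) " [LOW EXCITATION]" else ""
  ))
  invisible(x)
}
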