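#' Rotation matrix of a 3-marker rigid board
#'
#' The board carries markers 1 and 2 along its local x axis and marker 3
#' offset along its local y axis. The board axes are built by Gram-Schmidt:
#' `x = normalize(m2 - m1)`, `y = normalize((m3 - m1) orthogonal to x)`,
#' `z = x cross y`; the columns assemble the board-to-lab rotation. Exact for
#' rigid boards; for noisy markers a Procrustes (SVD) fit to the canonical
#' geometry is available.
#'
#' @param m1,m2,m3 Length-3 marker positions (mm, lab frame).
#' @param method `"gram_schmidt"` (default) or `"procrustes"`.
#' @param geometry For the Procrustes fit: 3 x 3 matrix of the canonical
#'   marker positions in the board frame (rows = markers, mm).
#' @return 3x3 rotation matrix mapping board-frame components to the lab frame.
#' @export
board_rotation <- function(m1, m2, m3, method = c("gram_schmidt", "procrustes"),
                           geometry = default_board_geometry()) {
  method <- match.arg(method)
  if (method == "gram_schmidt") {
    x <- m2 - m1
    nx <- sqrt(sum(x^2))
    if (nx < 1e-9) stop(degenerate_frame_error())
    x <- x / nx
    y <- (m3 - m1) - sum((m3 - m1) * x) * x
    ny <- sqrt(sum(y^2))
    if (ny < 1e-9) stop(degenerate_frame_error())
    y <- y / ny
    z <- c(x[2L] * y[3L] - x[3L] * y[2L],
           x[3L] * y[1L] - x[1L] * y[3L],
           x[1L] * y[2L] - x[2L] * y[1L])
    cbind(x, y, z, deparse.level = 0L)
  } else {
    P <- rbind(m1, m2, m3)
    Pc <- sweep(P, 2L, colMeans(P))
    if (qr(Pc, tol = 1e-7)$rank < 2L) stop(degenerate_frame_error())
    Gc <- sweep(geometry, 2L, colMeans(geometry))
    H <- crossprod(Gc, Pc)  # board -> lab covariance
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
}

degenerate_frame_error <- function() {
  structure(
    class = c("fingertap_degenerate_frame", "fingertap_error", "error", "condition"),
    list(message = "degenerate marker frame: markers collinear or coincident", call = NULL)
  )
}

#' Canonical T-board marker geometry
#'
#' Marker positions in the board (sensor) frame, mm: markers 1 and 2 along the
#' local x axis, marker 3 along y.
#'
#' @return 3 x 3 numeric matrix, rows = markers 1..3.
#' @export
default_board_geometry <- function() {
  rbind(c(0, 0, 0), c(50, 0, 0), c(0, 20, 0))
}

#' Relative rotation of the thumb board with respect to the index board
#'
#' `R = t(R2) %*% R1` (the inverse of a rotation is its transpose): the same
#' thumb-to-index map that the gyro path estimates, here obtained directly
#' from marker-board poses.
#'
#' @param R1 Thumb board-to-lab rotation.
#' @param R2 Index board-to-lab rotation.
#' @return 3x3 rotation matrix.
#' @export
relative_rotation <- function(R1, R2) {
  crossprod(R2, R1)
}

#' Check marker-board rigidity
#'
#' Flags frames where any pairwise marker distance deviates from its median by
#' more than the tolerance.
#'
#' @param markers n x 9 marker matrix (columns m1x..m3z, mm).
#' @param tol_mm Rigidity tolerance, mm.
#' @return Logical vector, `TRUE` where the board violates rigidity.
#' @export
check_rigidity <- function(markers, tol_mm = 2) {
  d12 <- sqrt(rowSums((markers[, 1:3, drop = FALSE] - markers[, 4:6, drop = FALSE])^2))
  d13 <- sqrt(rowSums((markers[, 1:3, drop = FALSE] - markers[, 7:9, drop = FALSE])^2))
  d23 <- sqrt(rowSums((markers[, 4:6, drop = FALSE] - markers[, 7:9, drop = FALSE])^2))
  abs(d12 - stats::median(d12)) > tol_mm |
    abs(d13 - stats::median(d13)) > tol_mm |
    abs(d23 - stats::median(d23)) > tol_mm
}

#' Reference tapping angle from marker boards
#'
#' Computes the raw angle from the marker-derived relative rotation at every
#' frame and returns the reference trace `theta_ref = -alpha + offset`, with
#' the constant offset chosen so that the angle is zero at the start of the
#' tapping sequence. Invariant to any whole-hand motion, because the relative
#' rotation cancels a common lab-frame rotation exactly.
#'
#' @param thumb_markers,index_markers n x 9 marker matrices (mm, lab frame).
#' @param t Time vector, seconds.
#' @param zero_index Sample at which the reference angle is set to zero
#'   (start of tapping; default 1).
#' @param realign Optional 3x3 realignment rotation from
#'   [realign_index_frame()], applied as on the gyro path.
#' @param method Passed to [board_rotation()].
#' @return A `tap_trace` with algorithm tag `"MOCAP"`.
#' @export
reference_angle_trace <- function(thumb_markers, index_markers, t,
                                  zero_index = 1L, realign = NULL,
                                  method = "gram_schmidt") {
  n <- nrow(thumb_markers)
  stopifnot(nrow(index_markers) == n, length(t) == n)
  alpha <- vapply(seq_len(n), function(i) {
    R1 <- board_rotation(thumb_markers[i, 1:3], thumb_markers[i, 4:6],
                         thumb_markers[i, 7:9], method = method)
    R2 <- board_rotation(index_markers[i, 1:3], index_markers[i, 4:6],
                         index_markers[i, 7:9], method = method)
    R <- relative_rotation(R1, R2)
    if (!is.null(realign)) R <- realign %*% R
    raw_angle(R)
  }, numeric(1L))
  tr <- new_tap_trace(t, alpha, "MOCAP", 1 / mean(diff(t)), 1L)
  tr$theta <- tr$theta - tr$theta[zero_index]
  tr
}
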