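#' Construct a gyro tapping session
#'
#' Container for one recorded sequence: a common timebase and paired tri-axial
#' angular-velocity series for the thumb and index-finger sensors, optionally
#' synchronized marker trajectories for the two rigid marker boards, and
#' free-form metadata. Angular velocities are stored in rad/s internally; all
#' file I/O is in deg/s (clinical convention).
#'
#' @param t Numeric vector of sample times in seconds (uniform).
#' @param w1 n x 3 matrix, thumb angular velocity (rad/s, sensor frame).
#' @param w2 n x 3 matrix, index-finger angular velocity (rad/s, sensor frame).
#' @param markers Optional list with elements `thumb` and `index`, each an
#'   n x 9 matrix of marker coordinates (mm, lab frame, columns
#'   m1x,m1y,m1z,m2x,...,m3z).
#' @param meta Optional named list of metadata (subject id, hand, task id, seed).
#' @return An object of class `tap_session`.
#' @export
tap_session <- function(t, w1, w2, markers = NULL, meta = list()) {
  w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  n <- length(t)
  if (n < 2L) stop("session needs at least two samples", call. = FALSE)
  if (nrow(w1) != n || nrow(w2) != n || ncol(w1) != 3L || ncol(w2) != 3L) {
    stop("w1 and w2 must be n x 3 matrices matching length(t)", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("time vector must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6) {
    stop("non-uniform sampling (jitter above 1 microsecond)", call. = FALSE)
  }
  if (!is.null(markers)) {
    stopifnot(is.list(markers), all(c("thumb", "index") %in% names(markers)))
    markers$thumb <- as.matrix(markers$thumb)
    markers$index <- as.matrix(markers$index)
    stopifnot(nrow(markers$thumb) == n, ncol(markers$thumb) == 9L,
              nrow(markers$index) == n, ncol(markers$index) == 9L)
  }
  structure(
    list(t = as.numeric(t), w1 = unname(w1), w2 = unname(w2),
         fs = 1 / mean(dt), dt = mean(dt), markers = markers, meta = meta),
    class = "tap_session"
  )
}

#' @export
print.tap_session <- function(x, ...) {
  cat(sprintf(
    "<tap_session> %d samples @ %.6g Hz (%.6g s)%s\n",
    length(x$t), x$fs, length(x$t) / x$fs,
    if (is.null(x$markers)) "" else ", with marker boards"
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a session
#' @param session A `tap_session`.
#' @return Integer sample count.
#' @export
session_length <- function(session) length(session$t)
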