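#' Average tapping period from the autocorrelation
#'
#' Lag of the first prominent peak of the autocorrelation of the mean-removed
#' tapping angle, searched between `min_lag_s` and `max_lag_s`. A peak
#' qualifies when it is a local maximum whose height exceeds `prominence`
#' times the zero-lag value; the first qualifying lag wins.
#'
#' @param theta Numeric tapping-angle series (any unit; invariant to constant
#'   offsets and sign flips).
#' @param dt Sampling step, seconds.
#' @param min_lag_s,max_lag_s Search range for the period, seconds.
#' @param prominence Minimum peak height as a fraction of the zero-lag value.
#' @return Estimated period in seconds.
#' @export
estimate_period <- function(theta, dt, min_lag_s = 0.2, max_lag_s = 3,
                            prominence = 0.3) {
  n <- length(theta)
  if (n * dt < 2) stop("need at least 2 s of signal to estimate a period", call. = FALSE)
  max_lag <- min(n - 2L, as.integer(ceiling(max_lag_s / dt)))
  a <- stats::acf(theta, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  lag0 <- a[1L]  # 1 by normalization
  k <- seq_along(a) - 1L
  interior <- seq.int(2L, length(a) - 1L)
  is_peak <- a[interior] > a[interior - 1L] & a[interior] >= a[interior + 1L]
  peaks <- interior[is_peak]
  peaks <- peaks[k[peaks] * dt >= min_lag_s & k[peaks] * dt <= max_lag_s &
                   a[peaks] >= prominence * lag0]
  if (!length(peaks)) stop(aperiodic_error())
  k[peaks[1L]] * dt
}

aperiodic_error <- function() {
  structure(
    class = c("fingertap_aperiodic", "fingertap_error", "error", "condition"),
    list(message = "no prominent autocorrelation peak: signal is not periodic in the searched lag range",
         call = NULL)
  )
}

#' Zero-phase averaging filter for the tapping angle
#'
#' Centered moving average with an odd window of about one eighth of the
#' tapping period. Removes contact bumps, vibrations and sensor noise while
#' preserving the tap peaks; edges are handled by shrinking the window, so the
#' filter is zero-phase everywhere.
#'
#' @param theta Numeric series.
#' @param period Tapping period, seconds.
#' @param dt Sampling step, seconds.
#' @param divisor Window width is `period / divisor` (default 8).
#' @return Smoothed series of the same length.
#' @export
smooth_theta <- function(theta, period, dt, divisor = 8) {
  w <- as.integer(round(period / divisor / dt))
  if (w %% 2L == 0L) w <- w + 1L
  if (w < 1L) w <- 1L
  moving_average(theta, w)
}

#' Identify individual taps
#'
#' The points of minima of the smoothed tapping angle are the starting and
#' ending points of individual taps. The average period serves as an educated
#' initial guess for a local heuristic search: candidate minima are samples
#' that minimize the smoothed angle over a window of `search_half_width` times
#' the period on each side; candidates closer than half a period are merged
#' (the deeper survives); segments whose amplitude falls below
#' `max(min_aperture, min_aperture_frac * median amplitude)` are merged into a
#' neighbour, so flat holds (skipped taps) do not split into spurious
#' zero-aperture taps. Final boundaries are refined to the minimum of the
#' unsmoothed series within half a smoothing window.
#'
#' @param theta Unsmoothed tapping-angle series, radians.
#' @param period Tapping period from [estimate_period()], seconds.
#' @param dt Sampling step, seconds.
#' @param theta_smooth Optional pre-smoothed series (default [smooth_theta()]).
#' @param search_half_width Half-width of the minima search window, as a
#'   fraction of the period.
#' @param min_separation Minimum boundary separation, fraction of the period.
#' @param min_aperture Absolute amplitude floor for a genuine tap, radians.
#' @param min_aperture_frac Relative amplitude floor (fraction of the median
#'   segment amplitude).
#' @param max_excess_frac A closure boundary must lie near the baseline: an
#'   interior boundary whose smoothed value exceeds the mean of its
#'   neighbouring boundaries by more than this fraction of the median segment
#'   amplitude is spurious (e.g. a wobble dip during a held-open skipped tap)
#'   and is dropped.
#' @param smooth_divisor Passed to [smooth_theta()] when `theta_smooth` is NULL.
#' @return A `tap_set`: list with `boundaries` (sample indices into `theta`,
#'   strictly increasing; tap k spans `boundaries[k] .. boundaries[k+1]`),
#'   `maxima` (one index per tap), `n_taps`, `period`, `dt`.
#' @export
find_tap_boundaries <- function(theta, period, dt, theta_smooth = NULL,
                                search_half_width = 0.35, min_separation = 0.5,
                                min_aperture = deg2rad(2), min_aperture_frac = 0.2,
                                max_excess_frac = 0.5, smooth_divisor = 8) {
  n <- length(theta)
  if (is.null(theta_smooth)) theta_smooth <- smooth_theta(theta, period, dt, smooth_divisor)
  w <- max(1L, as.integer(round(search_half_width * period / dt)))

  # candidates: local minimizers of the smoothed series over a +/- w window
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    theta_smooth[i] <= min(theta_smooth[lo:hi])
  }, logical(1L)))
  if (length(cand) < 2L) stop(no_taps_error())

  # merge candidates closer than min_separation * period, keeping the deeper
  sep <- as.integer(round(min_separation * period / dt))
  keep <- cand[1L]
  for (i in cand[-1L]) {
    last <- keep[length(keep)]
    if (i - last >= sep) {
      keep <- c(keep, i)
    } else if (theta_smooth[i] < theta_smooth[last]) {
      keep[length(keep)] <- i
    }
  }
  b <- keep
  if (length(b) < 2L) stop(no_taps_error())

  # drop interior boundaries sitting far above their neighbours (not closures)
  repeat {
    if (length(b) < 3L) break
    amp_med <- stats::median(vapply(seq_len(length(b) - 1L), function(k) {
      s <- theta_smooth[b[k]:b[k + 1L]]
      max(s) - min(s)
    }, numeric(1L)))
    i <- seq.int(2L, length(b) - 1L)
    excess <- theta_smooth[b[i]] - (theta_smooth[b[i - 1L]] + theta_smooth[b[i + 1L]]) / 2
    bad <- which(excess > max_excess_frac * amp_med)
    if (!length(bad)) break
    b <- b[-(i[bad[which.max(excess[bad])]])]
  }

  # amplitude-based merge: drop boundaries enclosing segments with no real tap
  seg_amp <- function(b) {
    vapply(seq_len(length(b) - 1L), function(k) {
      s <- theta_smooth[b[k]:b[k + 1L]]
      max(s) - min(s)
    }, numeric(1L))
  }
  repeat {
    if (length(b) < 3L) break
    amp <- seg_amp(b)
    floor_amp <- max(min_aperture, min_aperture_frac * stats::median(amp))
    bad <- which(amp < floor_amp)
    if (!length(bad)) break
    k <- bad[1L]
    # drop the shallower of the two boundaries of the degenerate segment
    drop_idx <- if (theta_smooth[b[k]] > theta_smooth[b[k + 1L]]) k else k + 1L
    # never drop an outermost boundary in favour of an interior one unless it is the shallow one
    b <- b[-drop_idx]
  }
  if (length(b) < 2L) stop(no_taps_error())
  amp <- seg_amp(b)
  if (all(amp < min_aperture)) stop(no_taps_error())

  # refine on the unsmoothed series within half a smoothing window
  ws <- as.integer(round(period / smooth_divisor / dt))
  half <- max(1L, ws %/% 2L)
  b <- vapply(b, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.min(theta[lo:hi]) - 1L
  }, integer(1L))
  b <- unique(b)
  if (length(b) < 2L) stop(no_taps_error())

  maxima <- vapply(seq_len(length(b) - 1L), function(k) {
    lo <- b[k] + 1L; hi <- b[k + 1L] - 1L
    if (hi < lo) return(b[k])
    lo + which.max(theta[lo:hi]) - 1L
  }, integer(1L))

  structure(
    list(boundaries = b, maxima = maxima, n_taps = length(b) - 1L,
         period = period, dt = dt, features = NULL),
    class = "tap_set"
  )
}

no_taps_error <- function() {
  structure(
    class = c("fingertap_no_taps", "fingertap_error", "error", "condition"),
    list(message = "fewer than two tap boundaries found: no taps in the signal", call = NULL)
  )
}

#' @export
print.tap_set <- function(x, ...) {
  cat(sprintf("<tap_set> %d taps, period %.3g s\n", x$n_taps, x$period))
  if (!is.null(x$features)) {
    cat(sprintf("  mean duration %.3g s, mean aperture %.1f deg\n",
                mean(x$features$duration_s), mean(rad2deg(x$features$aperture))))
  }
  invisible(x)
}

#' Remove the baseline from a tapping-angle series
#'
#' Subtracts the piecewise-linear interpolant through the per-tap minima
#' (the tap boundaries), extending with the nearest value before the first and
#' after the last boundary. After removal the angle is exactly zero at every
#' boundary: the fingers-closed position defines zero.
#'
#' @param theta Numeric series, radians.
#' @param tapset A `tap_set` from [find_tap_boundaries()].
#' @return Baseline-corrected series of the same length.
#' @export
remove_baseline <- function(theta, tapset) {
  b <- tapset$boundaries
  if (length(b) < 1L) stop("tap set is empty", call. = FALSE)
  if (length(b) == 1L) return(theta - theta[b])
  base <- stats::approx(x = b, y = theta[b], xout = seq_along(theta), rule = 2)$y
  theta - base
}

#' Per-tap features
#'
#' Fills the feature table of a tap set from the baseline-corrected angle:
#' duration, aperture (max minus min of the angle within the tap), and peak
#' opening/closing speeds (max/min of the central-difference derivative).
#'
#' @param theta_corrected Baseline-corrected angle, radians.
#' @param tapset A `tap_set`.
#' @param dt Sampling step, seconds.
#' @return The `tap_set` with a `features` data.frame: `tap`, `start`, `end`
#'   (indices), `t_start_s`, `t_end_s`, `duration_s`, `aperture` (rad),
#'   `peak_opening_speed`, `peak_closing_speed` (rad/s).
#' @export
extract_tap_features <- function(theta_corrected, tapset, dt) {
  b <- tapset$boundaries
  n <- length(theta_corrected)
  dtheta <- c(0, (theta_corrected[-(1:2)] - theta_corrected[seq_len(n - 2L)]) / (2 * dt), 0)
  k <- seq_len(tapset$n_taps)
  feat <- data.frame(
    tap = k,
    start = b[k],
    end = b[k + 1L],
    t_start_s = (b[k] - 1L) * dt,
    t_end_s = (b[k + 1L] - 1L) * dt,
    duration_s = (b[k + 1L] - b[k]) * dt,
    aperture = vapply(k, function(j) {
      s <- theta_corrected[b[j]:b[j + 1L]]
      max(s) - min(s)
    }, numeric(1L)),
    peak_opening_speed = vapply(k, function(j) max(dtheta[b[j]:b[j + 1L]]), numeric(1L)),
    peak_closing_speed = vapply(k, function(j) min(dtheta[b[j]:b[j + 1L]]), numeric(1L))
  )
  tapset$features <- feat
  tapset
}
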