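#' Intraclass correlation coefficient for one tap
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC (ICC(A,1))
#' between the estimated and the reference angle over one tap, computed from
#' the closed-form ANOVA mean squares of the paired series (time samples are
#' the targets, the two measurement systems the raters). Absolute agreement
#' penalizes constant offsets, which is the appropriate notion when the two
#' systems are supposed to report the same physical angle.
#'
#' @param x,y Equal-length paired numeric series (one tap, common timebase).
#' @param variant `"A1"` (absolute agreement, default) or `"C1"` (consistency).
#' @return ICC in `[-1, 1]`, or `NA` when both series have zero variance.
#' @export
icc_per_tap <- function(x, y, variant = c("A1", "C1")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("paired series must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  k <- 2
  m <- (mean(x) + mean(y)) / 2
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  ssr <- k * sum((row_means - m)^2)
  ssc <- n * sum((col_means - m)^2)
  sst <- sum((x - m)^2) + sum((y - m)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- if (variant == "A1") {
    msr + (k - 1) * mse + k * (msc - mse) / n
  } else {
    msr + (k - 1) * mse
  }
  if (abs(denom) < .Machine$double.eps * max(1, abs(msr))) return(NA_real_)
  (msr - mse) / denom
}

#' Root-mean-square error between two series
#'
#' @param x,y Equal-length numeric series.
#' @return `sqrt(mean((x - y)^2))`, in the unit of the inputs.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  sqrt(mean((x - y)^2))
}

#' Per-tap aperture errors between two tap sets
#'
#' Taps are paired by maximal temporal overlap (greedy, largest overlap first,
#' each tap used at most once). For each pair the absolute aperture error is
#' `|a_est - a_ref|` and the relative error divides by the reference aperture;
#' reference apertures below `min_ref_aperture` are excluded from the relative
#' error (division guard).
#'
#' @param taps_est,taps_ref `tap_set` objects with features filled
#'   ([extract_tap_features()]); `start`/`end` indices must refer to a common
#'   timebase.
#' @param min_ref_aperture Relative-error exclusion threshold, radians.
#' @return List with `abs_mean` (radians), `rel_mean` (dimensionless), and a
#'   per-pair data.frame `pairs` (`est`, `ref`, `overlap`, `abs_err`,
#'   `rel_err`).
#' @export
aperture_errors <- function(taps_est, taps_ref, min_ref_aperture = deg2rad(2)) {
  fe <- taps_est$features
  fr <- taps_ref$features
  if (is.null(fe) || is.null(fr)) stop("both tap sets need features", call. = FALSE)
  ov <- outer(seq_len(nrow(fe)), seq_len(nrow(fr)), function(i, j) {
    pmax(0, pmin(fe$end[i], fr$end[j]) - pmax(fe$start[i], fr$start[j]))
  })
  pairs <- data.frame(est = integer(), ref = integer(), overlap = numeric())
  while (any(ov > 0)) {
    ij <- arrayInd(which.max(ov), dim(ov))
    pairs <- rbind(pairs, data.frame(est = ij[1L], ref = ij[2L], overlap = ov[ij]))
    ov[ij[1L], ] <- 0
    ov[, ij[2L]] <- 0
  }
  if (!nrow(pairs)) {
    stop(structure(
      class = c("fingertap_pairing", "fingertap_error", "error", "condition"),
      list(message = "no tap pairs with temporal overlap", call = NULL)
    ))
  }
  pairs <- pairs[order(pairs$est), , drop = FALSE]
  a_est <- fe$aperture[pairs$est]
  a_ref <- fr$aperture[pairs$ref]
  pairs$abs_err <- abs(a_est - a_ref)
  pairs$rel_err <- ifelse(a_ref >= min_ref_aperture, pairs$abs_err / a_ref, NA_real_)
  list(
    abs_mean = mean(pairs$abs_err),
    rel_mean = if (all(is.na(pairs$rel_err))) NA_real_ else mean(pairs$rel_err, na.rm = TRUE),
    pairs = pairs
  )
}

#' Agreement report between an estimated trace and a reference
#'
#' Quantifies agreement over one sequence: per-tap ICC (averaged over taps),
#' per-tap RMS error (averaged over taps), and absolute/relative aperture
#' errors. Taps are defined on the estimate's segmentation and mirrored onto
#' the reference by time; both series must already share the gyro timebase.
#'
#' @param theta_est Baseline-corrected estimated angle, radians.
#' @param theta_ref Reference angle on the same timebase, radians.
#' @param tapset_est The estimate's `tap_set` with features.
#' @param tapset_ref Reference `tap_set` with features (e.g. from ground truth
#'   or from segmenting the reference); defaults to mirroring the estimate's
#'   boundaries onto `theta_ref`.
#' @param dt Sampling step, seconds.
#' @param icc_variant Passed to [icc_per_tap()].
#' @param min_ref_aperture Passed to [aperture_errors()], radians.
#' @return A list of class `tap_agreement`: `icc_mean`, `rmse_mean_deg`,
#'   `aperture_abs_err_mean_deg`, `aperture_rel_err_mean`, and per-tap vectors
#'   `icc`, `rmse_deg`.
#' @export
agreement_report <- function(theta_est, theta_ref, tapset_est, dt,
                             tapset_ref = NULL, icc_variant = "A1",
                             min_ref_aperture = deg2rad(2)) {
  stopifnot(length(theta_est) == length(theta_ref))
  b <- tapset_est$boundaries
  nt <- tapset_est$n_taps
  icc <- numeric(nt)
  rr <- numeric(nt)
  for (k in seq_len(nt)) {
    i <- b[k]:b[k + 1L]
    icc[k] <- icc_per_tap(theta_est[i], theta_ref[i], variant = icc_variant)
    rr[k] <- rmse(theta_est[i], theta_ref[i])
  }
  if (is.null(tapset_ref)) {
    tapset_ref <- extract_tap_features(theta_ref, tapset_est, dt)
  }
  ap <- aperture_errors(tapset_est, tapset_ref, min_ref_aperture = min_ref_aperture)
  structure(
    list(
      icc_mean = mean(icc, na.rm = TRUE),
      rmse_mean_deg = rad2deg(mean(rr)),
      aperture_abs_err_mean_deg = rad2deg(ap$abs_mean),
      aperture_rel_err_mean = ap$rel_mean,
      icc = icc,
      rmse_deg = rad2deg(rr),
      n_taps = nt
    ),
    class = "tap_agreement"
  )
}

#' @export
print.tap_agreement <- function(x, ...) {
  cat(sprintf(
    "<tap_agreement> %d taps: ICC %.3f, RMSE %.2f deg, aperture err %.2f deg (rel %.3f)\n",
    x$n_taps, x$icc_mean, x$rmse_mean_deg,
    x$aperture_abs_err_mean_deg, x$aperture_rel_err_mean
  ))
  invisible(x)
}
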