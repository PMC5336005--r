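#' Run the full processing pipeline on a session
#'
#' The complete chain: detect the autocalibration window, estimate the initial
#' thumb-to-index rotation, run the continuous algorithm, check the dominant
#' rotation axis and realign the index frame if needed, run the resetting
#' algorithm, select the algorithm by the 60-degree drift rule (or force one),
#' segment taps, remove the baseline, extract per-tap features, and, when
#' marker boards are present, compute agreement against the optical reference.
#' Stage failures are recovered into a partial report with explicit nulls.
#'
#' @param session A [tap_session()].
#' @param config Partial configuration (see [default_config()]).
#' @param algorithm `"auto"` (drift rule), `"alc"` or `"alr"`.
#' @return A list of class `tap_report`.
#' @export
run_pipeline <- function(session, config = NULL, algorithm = c("auto", "alc", "alr")) {
  algorithm <- match.arg(algorithm)
  cfg <- merge_config(config)
  report <- structure(
    list(ok = FALSE, failed_stage = NULL, error = NULL,
         calibration = NULL, realignment = NULL,
         drift_alc_deg = NULL, drift_alr_deg = NULL, algorithm = NULL,
         trace_alc = NULL, trace_alr = NULL, taps = NULL, agreement = NULL,
         config = cfg,
         version = as.character(utils::packageVersion("fingertap"))),
    class = "tap_report"
  )
  fail <- function(stage, e) {
    report$failed_stage <- stage
    report$error <- conditionMessage(e)
    report
  }

  cc <- cfg$calibration
  win <- tryCatch(
    detect_calibration_window(session, vigor_dps = cc$vigor_dps, mismatch = cc$mismatch,
                              min_duration_s = cc$min_duration_s, smooth_s = cc$smooth_s,
                              search_fraction = cc$search_fraction),
    error = function(e) e
  )
  if (inherits(win, "error")) return(fail("calibration_window", win))

  cal <- tryCatch(
    estimate_initial_rotation(session, win, cost_tol = cc$cost_tol, maxit = cc$maxit,
                              restart_deg = cc$restart_deg,
                              restart_rel_cost = cc$restart_rel_cost,
                              low_excitation_ratio = cc$low_excitation_ratio),
    error = function(e) e
  )
  if (inherits(cal, "error")) return(fail("calibration", cal))
  report$calibration <- list(
    euler_deg = rad2deg(cal$euler),
    R0 = cal$R0,
    residual_cost = cal$residual_cost,
    window_s = c(win$t_start, win$t_end),
    converged = cal$converged,
    low_excitation = cal$low_excitation
  )

  est <- tryCatch(
    estimate_angles(session, cal$R0, win, cfg),
    error = function(e) e
  )
  if (inherits(est, "error")) return(fail("angle_estimation", est))
  report$realignment <- list(applied = est$realign$applied, Q = est$realign$Q,
                             axis = est$realign$axis,
                             energy = est$realign$energy)
  report$drift_alc_deg <- rad2deg(est$trace_alc$final_drift)
  report$drift_alr_deg <- rad2deg(est$trace_alr$final_drift)
  report$trace_alc <- est$trace_alc
  report$trace_alr <- est$trace_alr
  report$algorithm <- switch(algorithm,
    auto = select_algorithm(est$trace_alc$final_drift,
                            threshold = deg2rad(cfg$angles$drift_threshold_deg)),
    alc = "AL-C",
    alr = "AL-R"
  )
  trace <- if (report$algorithm == "AL-C") est$trace_alc else est$trace_alr

  seg <- tryCatch(segment_trace(trace, cfg), error = function(e) e)
  if (inherits(seg, "error")) return(fail("segmentation", seg))
  report$theta_deg <- rad2deg(seg$theta_corrected)
  report$period_s <- seg$tapset$period
  f <- seg$tapset$features
  report$taps <- data.frame(
    tap_index = f$tap,
    t_start_s = trace$t[f$start],
    t_end_s = trace$t[f$end],
    duration_s = f$duration_s,
    aperture_deg = rad2deg(f$aperture),
    peak_open_dps = rad2deg(f$peak_opening_speed),
    peak_close_dps = rad2deg(f$peak_closing_speed)
  )
  report$trace <- trace
  report$tapset <- seg$tapset
  report$theta_corrected <- seg$theta_corrected

  if (!is.null(session$markers)) {
    agr <- tryCatch(
      mocap_agreement(session, trace, seg, est$realign$Q, win, cfg),
      error = function(e) e
    )
    if (inherits(agr, "error")) return(fail("agreement", agr))
    report$agreement <- agr
  }
  report$ok <- TRUE
  report
}

# AL-C with dominant-axis check and realignment, plus AL-R, on one session
estimate_angles <- function(session, R0, win, cfg) {
  start <- win$end
  n <- session_length(session)
  fs <- session$fs
  guard <- as.integer(round(cfg$angles$guard_s * fs))
  tap_start <- min(n, start + guard)

  alc <- run_alc(session, R0, start_index = start,
                 reorthonormalize_every = cfg$angles$reorthonormalize_every)
  wr_tap <- alc$wr[(tap_start - start + 1L):nrow(alc$wr), , drop = FALSE]
  # dominance assessed on the averaged relative angular velocity, so brief
  # contact transients (impacts, slips) cannot masquerade as the dominant axis
  sw <- max(1L, as.integer(round(cfg$angles$realign_smooth_s * fs)))
  wr_sm <- apply(wr_tap, 2L, moving_average, w = sw)
  realign <- realign_index_frame(wr_sm, session$dt,
                                 dominance_min = cfg$angles$realign_dominance_min)
  if (realign$applied) {
    session$w2 <- tcrossprod(session$w2, realign$Q)
    R0 <- realign$Q %*% R0
    alc <- run_alc(session, R0, start_index = start,
                   reorthonormalize_every = cfg$angles$reorthonormalize_every)
  }
  alr <- run_alr(session, R0, start_index = start)
  list(trace_alc = alc, trace_alr = alr, realign = realign,
       R0 = R0, tap_start = tap_start)
}

# period estimate, smoothing, boundaries, baseline, features for one trace
segment_trace <- function(trace, cfg) {
  sg <- cfg$segmentation
  dt <- 1 / trace$fs
  period <- estimate_period(trace$theta, dt, min_lag_s = sg$acf_min_lag_s,
                            max_lag_s = sg$acf_max_lag_s,
                            prominence = sg$acf_prominence)
  tapset <- find_tap_boundaries(trace$theta, period, dt,
                                search_half_width = sg$search_half_width,
                                min_separation = sg$min_separation,
                                min_aperture = deg2rad(sg$min_aperture_deg),
                                min_aperture_frac = sg$min_aperture_frac,
                                max_excess_frac = sg$max_excess_frac,
                                smooth_divisor = sg$smooth_divisor)
  theta_corrected <- remove_baseline(trace$theta, tapset)
  tapset <- extract_tap_features(theta_corrected, tapset, dt)
  tapset$features$t_start_s <- trace$t[tapset$features$start]
  tapset$features$t_end_s <- trace$t[tapset$features$end]
  list(period = period, tapset = tapset, theta_corrected = theta_corrected)
}

# agreement of a trace against the marker-board reference
mocap_agreement <- function(session, trace, seg, Q, win, cfg) {
  idx <- seq.int(trace$start_index, trace$start_index + length(trace$t) - 1L)
  guard <- as.integer(round(cfg$angles$guard_s * session$fs))
  zero_index <- min(length(idx), guard + 1L)
  ref <- reference_angle_trace(
    session$markers$thumb[idx, , drop = FALSE],
    session$markers$index[idx, , drop = FALSE],
    session$t[idx], zero_index = zero_index,
    realign = if (is.null(Q)) NULL else Q,
    method = cfg$mocap$board_method
  )
  agreement_report(seg$theta_corrected, ref$theta, seg$tapset, 1 / session$fs,
                   icc_variant = cfg$metrics$icc_variant,
                   min_ref_aperture = deg2rad(cfg$metrics$min_ref_aperture_deg))
}

#' @export
print.tap_report <- function(x, ...) {
  cat("<tap_report>\n")
  if (!is.null(x$failed_stage)) {
    cat(sprintf("  FAILED at stage '%s': %s\n", x$failed_stage, x$error))
    return(invisible(x))
  }
  cat(sprintf("  calibration: euler (%.1f, %.1f, %.1f) deg, window [%.2f, %.2f] s\n",
              x$calibration$euler_deg[1L], x$calibration$euler_deg[2L],
              x$calibration$euler_deg[3L],
              x$calibration$window_s[1L], x$calibration$window_s[2L]))
  cat(sprintf("  drift: AL-C %.1f deg, AL-R %.1f deg -> %s selected\n",
              x$drift_alc_deg, x$drift_alr_deg, x$algorithm))
  if (!is.null(x$realignment) && isTRUE(x$realignment$applied)) {
    cat("  index frame realigned to the dominant rotation axis\n")
  }
  if (!is.null(x$taps)) {
    cat(sprintf("  %d taps, mean aperture %.1f deg, mean duration %.2f s\n",
                nrow(x$taps), mean(x$taps$aperture_deg), mean(x$taps$duration_s)))
  }
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}

#' Evaluate a synthetic session against its ground truth
#'
#' Runs calibration and both angle algorithms on a simulated session, segments
#' each algorithm's trace, and scores it against the noise-free ground-truth
#' angle: mean per-tap ICC, mean per-tap RMS error, and absolute/relative
#' aperture errors with taps paired by temporal overlap. This is the
#' simulation surrogate for the validation against an optical reference.
#'
#' @param session A synthetic [tap_session()] carrying `truth`.
#' @param config Partial configuration.
#' @return One-row data.frame: pattern, seed, true/detected tap counts, drifts,
#'   selected algorithm, and icc/rmse/aperture-error columns for AL-C and AL-R.
#' @export
evaluate_session <- function(session, config = NULL) {
  if (is.null(session$truth)) stop("session carries no ground truth", call. = FALSE)
  cfg <- merge_config(config)
  cc <- cfg$calibration
  win <- detect_calibration_window(session, vigor_dps = cc$vigor_dps, mismatch = cc$mismatch,
                                   min_duration_s = cc$min_duration_s, smooth_s = cc$smooth_s,
                                   search_fraction = cc$search_fraction)
  cal <- estimate_initial_rotation(session, win, cost_tol = cc$cost_tol, maxit = cc$maxit,
                                   restart_deg = cc$restart_deg,
                                   restart_rel_cost = cc$restart_rel_cost,
                                   low_excitation_ratio = cc$low_excitation_ratio)
  est <- estimate_angles(session, cal$R0, win, cfg)

  score <- function(trace) {
    seg <- segment_trace(trace, cfg)
    idx <- seq.int(trace$start_index, trace$start_index + length(trace$t) - 1L)
    theta_true <- session$truth$theta[idx]
    agr <- agreement_report(
      seg$theta_corrected, theta_true, seg$tapset, 1 / session$fs,
      tapset_ref = truth_tapset(session, trace),
      icc_variant = cfg$metrics$icc_variant,
      min_ref_aperture = deg2rad(cfg$metrics$min_ref_aperture_deg)
    )
    list(seg = seg, agr = agr)
  }
  s_alc <- score(est$trace_alc)
  s_alr <- score(est$trace_alr)

  data.frame(
    pattern = session$truth$spec$pattern_id,
    seed = session$truth$seed,
    n_taps_true = session$truth$tap_count,
    n_taps_alc = s_alc$seg$tapset$n_taps,
    n_taps_alr = s_alr$seg$tapset$n_taps,
    drift_alc_deg = rad2deg(est$trace_alc$final_drift),
    drift_alr_deg = rad2deg(est$trace_alr$final_drift),
    algorithm = select_algorithm(est$trace_alc$final_drift,
                                 threshold = deg2rad(cfg$angles$drift_threshold_deg)),
    cal_error_rad = rotation_angle_between(cal$R0, session$truth$R_true),
    icc_alc = s_alc$agr$icc_mean,
    icc_alr = s_alr$agr$icc_mean,
    rmse_alc_deg = s_alc$agr$rmse_mean_deg,
    rmse_alr_deg = s_alr$agr$rmse_mean_deg,
    aperture_abs_alc_deg = s_alc$agr$aperture_abs_err_mean_deg,
    aperture_abs_alr_deg = s_alr$agr$aperture_abs_err_mean_deg,
    aperture_rel_alc = s_alc$agr$aperture_rel_err_mean,
    aperture_rel_alr = s_alr$agr$aperture_rel_err_mean,
    stringsAsFactors = FALSE
  )
}

# ground-truth tap set expressed in a trace's index space, with features
truth_tapset <- function(session, trace) {
  fs <- session$fs
  off <- trace$start_index - 1L
  b <- as.integer(round(session$truth$tap_starts_s * fs)) + 1L - off
  last_end <- as.integer(round(session$truth$tap_ends_s[length(session$truth$tap_ends_s)] * fs)) + 1L - off
  b <- c(b, last_end)
  b <- pmin(pmax(b, 1L), length(trace$t))
  b <- unique(b)
  ts <- structure(
    list(boundaries = b, maxima = integer(length(b) - 1L),
         n_taps = length(b) - 1L, period = 1 / session$truth$spec$tap_rate,
         dt = 1 / fs, features = NULL),
    class = "tap_set"
  )
  idx <- seq.int(trace$start_index, trace$start_index + length(trace$t) - 1L)
  extract_tap_features(session$truth$theta[idx], ts, 1 / fs)
}

# angle of the relative rotation between two rotation matrices (radians)
rotation_angle_between <- function(Ra, Rb) {
  tr <- sum(diag(crossprod(Rb, Ra)))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

#' Simulation surrogate battery
#'
#' Generates a battery of synthetic sessions (by default two per tapping
#' pattern), runs [evaluate_session()] on each, and returns the per-session
#' metric table. Averaging its columns reproduces the headline agreement
#' figures of the validation study design (per-tap ICC, RMS error, aperture
#' errors, for both algorithms).
#'
#' @param seeds Integer vector of session seeds (one session per seed).
#' @param patterns Pattern ids, recycled to `length(seeds)`.
#' @param sensor A [sensor_spec()] applied to every session.
#' @param config Partial pipeline configuration.
#' @param markers Emit (unused) marker streams (default FALSE for speed).
#' @return data.frame with one row per session (see [evaluate_session()]).
#' @export
validation_battery <- function(seeds = 1:22,
                               patterns = rep(1:11, length.out = length(seeds)),
                               sensor = sensor_spec(), config = NULL,
                               markers = FALSE) {
  patterns <- rep(patterns, length.out = length(seeds))
  rows <- lapply(seq_along(seeds), function(i) {
    ses <- generate_session(pattern_spec(patterns[i]), sensor = sensor,
                            seed = seeds[i], markers = markers)
    evaluate_session(ses, config = config)
  })
  do.call(rbind, rows)
}
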