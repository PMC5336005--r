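#' Read a gyro session from CSV
#'
#' Expects the documented column dialect: header
#' `t_s,w1x,w1y,w1z,w2x,w2y,w2z`, times in seconds, angular velocities in
#' deg/s (converted to rad/s internally). Sampling uniformity and time
#' monotonicity are validated; isolated missing samples (gaps up to
#' `max_nan_gap_s`) are linearly interpolated with a warning, longer runs are
#' an error.
#'
#' @param path CSV file path.
#' @param max_nan_gap_s Longest interpolatable missing-data run, seconds.
#' @return A [tap_session()].
#' @export
read_gyro_csv <- function(path, max_nan_gap_s = 0.025) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_s", "w1x", "w1y", "w1z", "w2x", "w2y", "w2z")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  t <- df$t_s
  if (any(diff(t) <= 0)) stop("non-monotone time column", call. = FALSE)
  w <- as.matrix(df[, c("w1x", "w1y", "w1z", "w2x", "w2y", "w2z")])
  if (anyNA(w)) {
    dt <- stats::median(diff(t))
    max_run <- max(rle(rowSums(is.na(w)) > 0)$lengths[rle(rowSums(is.na(w)) > 0)$values], 0)
    if (max_run * dt > max_nan_gap_s) {
      stop(sprintf("missing-data run of %.0f ms exceeds %.0f ms", max_run * dt * 1000,
                   max_nan_gap_s * 1000), call. = FALSE)
    }
    warning("interpolating isolated missing samples", call. = FALSE)
    for (j in seq_len(ncol(w))) {
      if (anyNA(w[, j])) w[, j] <- stats::approx(t[!is.na(w[, j])], w[!is.na(w[, j]), j],
                                                 xout = t, rule = 2)$y
    }
  }
  tap_session(t, deg2rad(w[, 1:3]), deg2rad(w[, 4:6]))
}

#' Write a gyro session to CSV
#'
#' Inverse of [read_gyro_csv()] (deg/s on disk); round-trips exactly at the
#' printed precision.
#'
#' @param session A [tap_session()].
#' @param path Output path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_gyro_csv <- function(session, path, digits = 10) {
  df <- data.frame(
    t_s = session$t,
    w1x = rad2deg(session$w1[, 1L]), w1y = rad2deg(session$w1[, 2L]), w1z = rad2deg(session$w1[, 3L]),
    w2x = rad2deg(session$w2[, 1L]), w2y = rad2deg(session$w2[, 2L]), w2z = rad2deg(session$w2[, 3L])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fingertap gyro CSV v1: t_s in s, angular velocities in deg/s", con)
  utils::write.csv(format(df, digits = digits, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read marker-board trajectories from CSV
#'
#' Dialect: `t_s` then 18 coordinate columns (mm, lab frame): thumb markers
#' 1-3 then index markers 1-3, each as x,y,z.
#'
#' @param path CSV file path.
#' @return List with `t`, `thumb` (n x 9), `index` (n x 9).
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  cols <- marker_columns()
  if (!all(c("t_s", cols) %in% names(df))) {
    stop("marker CSV must have columns t_s plus ", paste(cols, collapse = ","), call. = FALSE)
  }
  list(t = df$t_s,
       thumb = as.matrix(df[, cols[1:9]]),
       index = as.matrix(df[, cols[10:18]]))
}

marker_columns <- function() {
  c(t(outer(c("t1", "t2", "t3", "i1", "i2", "i3"), c("x", "y", "z"), paste0)))
}

#' Write marker-board trajectories to CSV
#'
#' @param session A [tap_session()] carrying `markers`.
#' @param path Output path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(session, path, digits = 10) {
  if (is.null(session$markers)) stop("session has no marker streams", call. = FALSE)
  m <- cbind(session$markers$thumb, session$markers$index)
  colnames(m) <- marker_columns()
  df <- data.frame(t_s = session$t, m, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fingertap marker CSV v1: t_s in s, marker coordinates in mm (lab frame)", con)
  utils::write.csv(format(df, digits = digits, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the ground-truth bundle of a synthetic session to JSON
#'
#' @param session A synthetic [tap_session()] from [generate_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(session, path) {
  tr <- session$truth
  if (is.null(tr)) stop("session carries no ground truth", call. = FALSE)
  payload <- list(
    theta_deg = rad2deg(tr$theta),
    tap_starts_s = tr$tap_starts_s,
    tap_ends_s = tr$tap_ends_s,
    tap_count = tr$tap_count,
    events = tr$events,
    R_true = tr$R_true,
    mount_euler_deg = rad2deg(tr$mount_euler),
    tapping_start_s = tr$tapping_start_s,
    seed = tr$seed,
    pattern = unclass(tr$spec),
    sensor = unclass(tr$sensor)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth bundle written by [write_truth_json()]
#'
#' @param path JSON path.
#' @return List mirroring the written payload, with angles back in radians
#'   (`theta`, `mount_euler`) and `R_true` as a matrix.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$theta <- deg2rad(x$theta_deg)
  x$mount_euler <- deg2rad(x$mount_euler_deg)
  x$R_true <- matrix(unlist(x$R_true), 3L, 3L)
  x
}

#' Export an angle trace as CSV
#'
#' Columns: `t_s`, `alpha_deg`, `theta_deg`, `algorithm`.
#'
#' @param trace A `tap_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t_s = trace$t, alpha_deg = rad2deg(trace$alpha),
                   theta_deg = rad2deg(trace$theta), algorithm = trace$algorithm)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a tap set as TSV
#'
#' Columns: `tap_index`, `t_start_s`, `t_end_s`, `duration_s`, `aperture_deg`,
#' `peak_open_dps`, `peak_close_dps`.
#'
#' @param tapset A `tap_set` with features.
#' @param path Output path.
#' @param t Optional time vector of the underlying trace (maps indices to
#'   absolute seconds; defaults to the feature table's own times).
#' @return `path`, invisibly.
#' @export
write_taps_tsv <- function(tapset, path, t = NULL) {
  f <- tapset$features
  if (is.null(f)) stop("tap set has no features; run extract_tap_features() first", call. = FALSE)
  t_start <- if (is.null(t)) f$t_start_s else t[f$start]
  t_end <- if (is.null(t)) f$t_end_s else t[f$end]
  df <- data.frame(
    tap_index = f$tap, t_start_s = t_start, t_end_s = t_end,
    duration_s = f$duration_s,
    aperture_deg = rad2deg(f$aperture),
    peak_open_dps = rad2deg(f$peak_opening_speed),
    peak_close_dps = rad2deg(f$peak_closing_speed)
  )
  utils::write.table(format(df, digits = 8, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a session report to JSON
#'
#' @param report A `tap_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

report_payload <- function(report) {
  r <- unclass(report)
  # drop bulky per-sample vectors; summaries and tables stay
  r$trace_alc <- trace_summary(r$trace_alc)
  r$trace_alr <- trace_summary(r$trace_alr)
  r$theta_deg <- NULL
  r
}

trace_summary <- function(trace) {
  if (is.null(trace)) return(NULL)
  list(
    algorithm = trace$algorithm,
    t_start_s = trace$t[1L],
    t_end_s = trace$t[length(trace$t)],
    n = length(trace$t),
    final_drift_deg = rad2deg(trace$final_drift),
    theta_min_deg = rad2deg(min(trace$theta)),
    theta_max_deg = rad2deg(max(trace$theta))
  )
}
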