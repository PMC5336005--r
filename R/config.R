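#' Default pipeline configuration
#'
#' Every tunable threshold of the processing chain, with its default. Values
#' can be overridden per sequence (the manual-correction hook for difficult
#' recordings): pass a nested list to [run_pipeline()] or a JSON file to the
#' command line; unnamed fields keep their defaults.
#'
#' @return Nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    calibration = list(
      vigor_dps = 30,            # both sensors must move faster than this
      mismatch = 0.1,            # max relative magnitude mismatch
      min_duration_s = 0.5,      # minimum window length
      smooth_s = 0.05,           # magnitude smoothing before thresholding
      search_fraction = 0.5,     # search only the first part of the recording
      cost_tol = 1e-10,
      maxit = 5000,
      restart_deg = 45,
      restart_rel_cost = 1e-6,
      low_excitation_ratio = 0.01
    ),
    angles = list(
      guard_s = 0.25,            # gap between calibration end and tapping segment
      drift_threshold_deg = 60,  # above this AL-C drift, AL-R is selected
      realign_dominance_min = 0.4,
      realign_smooth_s = 0.1,    # averaging before the dominant-axis decision
      reorthonormalize_every = 0
    ),
    segmentation = list(
      acf_min_lag_s = 0.2,
      acf_max_lag_s = 3,
      acf_prominence = 0.3,
      smooth_divisor = 8,        # averaging window = period / divisor
      search_half_width = 0.35,  # minima search half-width, fraction of period
      min_separation = 0.5,      # minimum boundary spacing, fraction of period
      min_aperture_deg = 2,
      min_aperture_frac = 0.2,
      max_excess_frac = 0.5
    ),
    metrics = list(
      icc_variant = "A1",        # two-way random, absolute agreement, single measures
      min_ref_aperture_deg = 2   # relative-error division guard
    ),
    mocap = list(
      rigidity_tol_mm = 2,
      board_method = "gram_schmidt"
    )
  )
}

#' Merge a partial configuration into the defaults
#'
#' @param config Partial nested list (possibly NULL).
#' @param base Base configuration (default [default_config()]).
#' @return Complete configuration list.
#' @export
merge_config <- function(config = NULL, base = default_config()) {
  if (is.null(config)) return(base)
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(config[[nm]], base[[nm]])
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}
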