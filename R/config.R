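#' Pipeline configuration
#'
#' All tunable constants of both pipelines, pinned by default to the
#' published values: sleep scored at D < 1; 25 degC temperature veto; 25 lux
#' light veto; 36-min (10% of 6 h) circadian overlap; 60-s touch bins; 5%
#' per hour smoothing; 2-h gap threshold.  Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `tapsleep_config`.
#' @export
tapsleep_config <- function(...) {
  defaults <- list(
    activity.cutoff_hz = 2,
    ck.weights = ck_weights()$weights,
    ck.scale = ck_weights()$scale,
    ck.threshold = 1,
    candidate.min_duration_min = 30,
    candidate.wake_tolerance_min = 5,
    veto.temp_c = 25,
    veto.light_lux = 25,
    veto.overlap_min = 36,
    tap.bin_seconds = 60,
    tap.smooth_frac = 0.05,
    tap.smooth_window_min = 60,
    tap.min_gap_hours = 2,
    tap.min_overlap_min = 36,
    cosinor.bin_minutes = 60,
    cosinor.per_cycle = FALSE,
    metrics.linearize_cutoff_h = 10,
    metrics.profile_bin_min = 3,
    metrics.profile_horizon_min = 240,
    metrics.d_step = 0.25,
    metrics.d_cap = 7
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "tapsleep_config_error")
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = c("tapsleep_config", "list"))
}

#' Read configuration overrides from a YAML key-value file
#'
#' Flat `key: value` pairs using the key names of [tapsleep_config()]
#' (e.g. `ck.threshold: 1`); `ck.weights` may be a 7-element list.
#'
#' @param path path to the file, or `NULL` for pure defaults.
#' @return a `tapsleep_config` list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(tapsleep_config())
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$ck.weights)) vals$ck.weights <- as.numeric(vals$ck.weights)
  do.call(tapsleep_config, vals)
}
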