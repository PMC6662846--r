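#' Pinned validation scenarios
#'
#' A named list of [subject_scenario()]s covering the behavioural regimes
#' the pipelines must handle, each with its own seed:
#'
#' * `clean_sleeper` — no nocturnal touches; the phone is put down 1 s
#'   before lights-out and picked up 1 s after waking.  Full-pipeline
#'   ground-truth recovery and SFF = 1 by construction.
#' * `phone_in_bed` — touch rate decaying linearly from 40/h to 0 over the
#'   2 h after onset, mirrored before wake: the phone accompanies falling
#'   asleep and waking up.
#' * `nonwear_night` — the watch is taken off for the whole night and left
#'   on the nightstand; near-body temperature drops to 22 degC.
#' * `low_user` — ~1.8k touches/day (below the ~3.2k/day engagement level
#'   at which tappigraphy errors change sign).
#' * `high_user` — ~5.1k touches/day.
#' * `fragmented` — brief phone checks every hour through the night.
#'
#' @param n_days days per scenario, default 7.
#' @return a named list of `subject_scenario` objects with distinct seeds.
#' @export
scenario_suite <- function(n_days = 7) {
  list(
    clean_sleeper = subject_scenario(
      n_days = n_days, seed = 101,
      nocturnal_touch_model = list(type = "none")),
    phone_in_bed = subject_scenario(
      n_days = n_days, seed = 102,
      nocturnal_touch_model = list(
        list(type = "post_onset_decay", rate = 40, duration = 2),
        list(type = "pre_wake_ramp", rate = 40, duration = 2))),
    nonwear_night = subject_scenario(
      n_days = n_days, seed = 103,
      nonwear_episodes = tibble::tibble(
        day = seq_len(n_days), start_clock_h = 23, duration_h = 9.5)),
    low_user = subject_scenario(
      n_days = n_days, seed = 104, touch_rate_day = 110),
    high_user = subject_scenario(
      n_days = n_days, seed = 105, touch_rate_day = 320),
    fragmented = subject_scenario(
      n_days = n_days, seed = 106,
      nocturnal_touch_model = list(type = "hourly_checks", interval_h = 1,
                                   burst = 1))
  )
}
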