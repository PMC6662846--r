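#' Extract putative sleep periods from minute-wise sleep/wake labels
#'
#' Maximal runs of sleep-scored minutes are found and runs separated by
#' embedded wake (or unknown) interruptions of at most `wake_tolerance_min`
#' minutes are merged.  A merged run qualifies as a candidate if it lasts at
#' least `min_duration_min`.  Onset is the first sleep minute; wake is the
#' minute after the last sleep minute (half-open).  Candidates whose span
#' contains more than `max_missing_frac` unknown minutes are dropped with a
#' warning.
#'
#' @param scores tibble with columns `minute`, `asleep` as returned by
#'   [score_sleep_wake()].
#' @param min_duration_min minimum candidate length, minutes (default 30).
#' @param wake_tolerance_min longest embedded interruption to bridge,
#'   minutes (default 5).
#' @param max_missing_frac largest tolerated fraction of unknown minutes
#'   inside a candidate (default 0.10).
#' @return a tibble with columns `onset`, `wake`, `duration_h`.
#' @export
extract_candidate_periods <- function(scores, min_duration_min = 30,
                                      wake_tolerance_min = 5,
                                      max_missing_frac = 0.10) {
  s <- scores$asleep
  sleep <- !is.na(s) & s
  r <- rle(sleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 0) {
    merged_start <- runs$start[1]
    out_s <- integer(0); out_e <- integer(0)
    prev_end <- runs$end[1]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        gap <- runs$start[i] - prev_end - 1L
        if (gap <= wake_tolerance_min) {
          prev_end <- runs$end[i]
        } else {
          out_s <- c(out_s, merged_start); out_e <- c(out_e, prev_end)
          merged_start <- runs$start[i]; prev_end <- runs$end[i]
        }
      }
    }
    out_s <- c(out_s, merged_start); out_e <- c(out_e, prev_end)
    runs <- tibble::tibble(start = out_s, end = out_e)
  }
  runs <- runs[(runs$end - runs$start + 1L) >= min_duration_min, , drop = FALSE]
  if (nrow(runs) > 0) {
    miss_frac <- vapply(seq_len(nrow(runs)), function(i) {
      mean(is.na(s[runs$start[i]:runs$end[i]]))
    }, numeric(1))
    if (any(miss_frac > max_missing_frac)) {
      warn(sprintf("%d candidate sleep period(s) dropped: > %.0f%% of minutes missing",
                   sum(miss_frac > max_missing_frac), 100 * max_missing_frac))
      runs <- runs[miss_frac <= max_missing_frac, , drop = FALSE]
    }
  }
  onset <- scores$minute[runs$start]
  wake <- scores$minute[runs$end] + 60
  tibble::tibble(onset = onset, wake = wake,
                 duration_h = as.numeric(wake - onset, units = "hours"))
}

window_median <- function(env, value_col, onset, wake) {
  time_col <- if ("minute" %in% names(env)) "minute" else "time"
  inside <- env[[time_col]] >= onset & env[[time_col]] < wake
  v <- env[[value_col]][inside]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  median(v)
}

#' Temperature (non-wear) veto
#'
#' A putative sleep period whose median near-body temperature is strictly
#' below `min_median_c` is flagged: the watch was most likely off the body.
#' Windows with no temperature coverage are flagged conservatively, with a
#' warning.
#'
#' @param window one-row tibble (or list) with `onset` and `wake`.
#' @param env a data frame carrying temperature: either a raw
#'   `actigraphy_recording` (columns `time`, `temperature`) or an
#'   `activity_series` (columns `minute`, `temp_median`).
#' @param min_median_c threshold in degrees C, default 25.
#' @return `TRUE` if the window is vetoed.
#' @export
veto_temperature <- function(window, env, min_median_c = 25) {
  col <- if ("temp_median" %in% names(env)) "temp_median" else "temperature"
  med <- window_median(env, col, window$onset, window$wake)
  if (is.na(med)) {
    warn("no temperature coverage for putative sleep period; vetoing conservatively")
    return(TRUE)
  }
  med < min_median_c
}

#' Ambient-light veto
#'
#' A putative sleep period is flagged unless its median ambient light drops
#' strictly below `max_median_lux` — a median at or above the threshold
#' indicates a lit environment (e.g. a daytime nap).  Windows with no light
#' coverage are flagged conservatively, with a warning.
#'
#' @inheritParams veto_temperature
#' @param max_median_lux threshold in lux, default 25.
#' @return `TRUE` if the window is vetoed.
#' @export
veto_light <- function(window, env, max_median_lux = 25) {
  col <- if ("light_median" %in% names(env)) "light_median" else "light"
  med <- window_median(env, col, window$onset, window$wake)
  if (is.na(med)) {
    warn("no light coverage for putative sleep period; vetoing conservatively")
    return(TRUE)
  }
  med >= max_median_lux
}

#' Circadian-overlap veto
#'
#' A putative sleep period must contain at least `min_overlap_min` minutes
#' of overlap (inclusive) with the 6-h circadian low-activity window of its
#' cycle; otherwise it is flagged.
#'
#' @param window one-row tibble (or list) with `onset` and `wake`.
#' @param low_window one-row tibble with `start` and `end`, or `NULL` if no
#'   low-activity window exists for the cycle (then the window is vetoed
#'   with a warning).
#' @param min_overlap_min minimum overlap in minutes, default 36.
#' @return `TRUE` if the window is vetoed.
#' @export
veto_overlap <- function(window, low_window, min_overlap_min = 36) {
  if (is.null(low_window) || nrow(low_window) == 0) {
    warn("no circadian low-activity window for this cycle; vetoing conservatively")
    return(TRUE)
  }
  ov <- overlap_minutes(window$onset, window$wake,
                        low_window$start[1], low_window$end[1])
  ov < min_overlap_min
}

#' Apply all three vetoes to candidate sleep periods
#'
#' @param candidates tibble from [extract_candidate_periods()].
#' @param env environment data for the temperature and light vetoes (see
#'   [veto_temperature()]).
#' @param low_windows tibble of per-cycle low-activity windows from
#'   [low_activity_windows()].
#' @param config a [tapsleep_config()] list supplying the thresholds.
#' @return `candidates` with added columns `cycle`, `veto_flags` (comma
#'   separated; `""` when the window survives) and `overlap_min`.
#' @export
apply_vetoes <- function(candidates, env, low_windows,
                         config = tapsleep_config()) {
  n <- nrow(candidates)
  flags <- character(n)
  overlap <- numeric(n)
  cyc <- cycle_of(candidates$onset + as.numeric(candidates$wake - candidates$onset) / 2)
  for (i in seq_len(n)) {
    w <- candidates[i, ]
    f <- character(0)
    if (veto_temperature(w, env, config$veto.temp_c)) f <- c(f, "temperature")
    if (veto_light(w, env, config$veto.light_lux)) f <- c(f, "light")
    lw <- low_windows[low_windows$cycle == cyc[i], , drop = FALSE]
    if (veto_overlap(w, lw, config$veto.overlap_min)) f <- c(f, "overlap")
    flags[i] <- paste(f, collapse = ",")
    overlap[i] <- if (nrow(lw) > 0) {
      overlap_minutes(w$onset, w$wake, lw$start[1], lw$end[1])
    } else 0
  }
  candidates$cycle <- cyc
  candidates$veto_flags <- flags
  candidates$overlap_min <- overlap
  candidates
}

#' Select at most one sleep window per noon-to-noon cycle
#'
#' Vetoed candidates are excluded; among the survivors of each cycle the
#' longest window wins, ties broken by larger circadian overlap, then by
#' earlier onset.
#'
#' @param candidates tibble from [apply_vetoes()].
#' @param source label recorded in the night table (default "actigraphy").
#' @return a [night_table()] with one row per cycle that yielded a window.
#' @export
select_nightly_sleep <- function(candidates, source = "actigraphy") {
  surv <- candidates[candidates$veto_flags == "", , drop = FALSE]
  if (nrow(surv) == 0) return(night_table())
  surv <- surv |>
    dplyr::group_by(.data$cycle) |>
    dplyr::arrange(dplyr::desc(.data$duration_h),
                   dplyr::desc(.data$overlap_min), .data$onset,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  night_table(night_id = surv$cycle, source = rep(source, nrow(surv)),
              onset = surv$onset, wake = surv$wake,
              veto_flags = rep("", nrow(surv)),
              overlap_min = surv$overlap_min)
}

#' Full actigraphy sleep pipeline
#'
#' Raw recording to night table: per-minute activity, Cole-Kripke D,
#' sleep/wake scoring, candidate extraction, cosinor low-activity windows,
#' vetoes, and nightly selection.
#'
#' @param recording an `actigraphy_recording`.
#' @param config a [tapsleep_config()] list.
#' @param activity optionally, a precomputed `activity_series` (used by the
#'   chunked scorer); when supplied the recording may be `NULL`.
#' @return a list of class `tapsleep_actigraphy` with elements `nights`
#'   (a [night_table()]), `activity`, `d`, `candidates`, `cosinor` and
#'   `low_windows`.
#' @export
actigraphy_sleep <- function(recording, config = tapsleep_config(),
                             activity = NULL) {
  if (is.null(activity)) {
    activity <- compute_activity(recording, cutoff_hz = config$activity.cutoff_hz)
  }
  d <- cole_kripke_d(activity, config$ck.weights, config$ck.scale)
  scores <- score_sleep_wake(d, config$ck.threshold)
  cand <- extract_candidate_periods(scores,
                                    config$candidate.min_duration_min,
                                    config$candidate.wake_tolerance_min)
  fit_data <- tibble::tibble(time = activity$minute, value = activity$counts)
  fit_data <- fit_data[!is.na(fit_data$value), ]
  fit <- cosinor_fit(fit_data)
  cycles <- sort(unique(cycle_of(activity$minute)))
  low <- if (isTRUE(config$cosinor.per_cycle)) {
    per_cycle_low_windows(fit_data, cycles)
  } else {
    low_activity_windows(fit, cycles)
  }
  cand <- apply_vetoes(cand, activity, low, config)
  nights <- select_nightly_sleep(cand, source = "actigraphy")
  structure(list(nights = nights, activity = activity, d = d,
                 candidates = cand, cosinor = fit, low_windows = low),
            class = "tapsleep_actigraphy")
}
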