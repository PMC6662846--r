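#' Define a synthetic subject scenario
#'
#' All study conditions for one simulated subject: the nightly sleep
#' schedule and its jitter, wrist-motility levels awake and asleep, the
#' smartphone touch process, nocturnal touch behaviour, non-wear episodes,
#' and the light/temperature schedules.  The defaults emulate a diurnal
#' young-adult sleeper wearing the watch continuously: 50 Hz sampling,
#' lights-out 23:30, wake 07:30 with 20-min nightly jitter, daytime wrist
#' noise calibrated so the Cole-Kripke D score sits at free-living daytime
#' levels (~4-6; D > 7 is vigorous activity) and well below 1 in sleep
#' (~0.1-0.5), and ~3000 touches/day.
#'
#' @param n_days number of noon-to-noon cycles to simulate.
#' @param start_date calendar date of the first cycle's noon.
#' @param onset_clock,wake_clock nightly schedule, "HH:MM" or fractional
#'   hours; onset must fall after noon, wake before noon.
#' @param jitter_sd_min per-night Gaussian jitter SD of onset and wake,
#'   minutes (clamped at +-120 min).
#' @param sample_rate actigraphy sampling rate, Hz.
#' @param day_noise_g,sleep_noise_g per-axis dynamic acceleration noise SD
#'   (g) awake / asleep.
#' @param circadian_mod fractional 24-h cosinor modulation of daytime
#'   motility.
#' @param transition_min motility transition length at onset/wake: the
#'   1%-99% span of the logistic ramp, minutes.
#' @param touch_rate_day daytime touch rate, events/h.
#' @param rest_boost touch-rate multiplier in the wakeful-rest half hours
#'   just before lights-out and just after waking.
#' @param rest_window_min length of those wakeful-rest windows, minutes.
#' @param anchor_touches place one touch 1 s before each true onset and 1 s
#'   after each true wake (phone put down at lights-out, checked on
#'   waking).
#' @param nocturnal_touch_model `list(type = "none")`, or one of / a list
#'   of: `list(type = "post_onset_decay", rate, duration)` (touch rate
#'   decaying linearly from `rate`/h to 0 over `duration` h after onset),
#'   `list(type = "pre_wake_ramp", rate, duration)` (mirrored before
#'   wake), `list(type = "hourly_checks", interval_h, burst)` (brief phone
#'   checks through the night).
#' @param nonwear_episodes `NULL`, or a data frame with columns `day`
#'   (cycle index), `start_clock_h`, `duration_h`: the watch is off-body
#'   (temperature drops to `temp_nonwear`, motility to near zero).
#' @param light_day,light_night ambient light, lux.
#' @param temp_wear,temp_nonwear near-body temperature, degrees C.
#' @param diary_noise_min SD of diary reporting error, minutes.
#' @param seed integer RNG seed; every stream is reproducible from it.
#' @return a list of class `subject_scenario`.
#' @export
subject_scenario <- function(n_days = 7,
                             start_date = as.Date("2024-03-04"),
                             onset_clock = "23:30", wake_clock = "07:30",
                             jitter_sd_min = 20,
                             sample_rate = 50,
                             day_noise_g = 0.09, sleep_noise_g = 0.003,
                             circadian_mod = 0.2,
                             transition_min = 10,
                             touch_rate_day = 180,
                             rest_boost = 2, rest_window_min = 30,
                             anchor_touches = TRUE,
                             nocturnal_touch_model = list(type = "none"),
                             nonwear_episodes = NULL,
                             light_day = 250, light_night = 1,
                             temp_wear = 31, temp_nonwear = 22,
                             diary_noise_min = 10,
                             seed = 1) {
  onset_h <- parse_clock(onset_clock)
  wake_h <- parse_clock(wake_clock)
  if (onset_h <= 12 || onset_h >= 36 || wake_h >= 12 || wake_h < 0) {
    abort("scenario requires onset after noon and wake before the next noon",
          class = "tapsleep_scenario_error")
  }
  if (wake_h + 24 <= onset_h) {
    abort("scenario is infeasible: wake must come after onset",
          class = "tapsleep_scenario_error")
  }
  stopifnot(touch_rate_day >= 0, day_noise_g >= 0, sleep_noise_g >= 0,
            n_days >= 1, sample_rate >= 5)
  if (!is.null(nocturnal_touch_model$type)) {
    nocturnal_touch_model <- list(nocturnal_touch_model)
  }
  structure(list(
    n_days = n_days, start_date = as.Date(start_date),
    onset_h = onset_h, wake_h = wake_h, jitter_sd_min = jitter_sd_min,
    sample_rate = sample_rate,
    day_noise_g = day_noise_g, sleep_noise_g = sleep_noise_g,
    circadian_mod = circadian_mod, transition_min = transition_min,
    touch_rate_day = touch_rate_day, rest_boost = rest_boost,
    rest_window_min = rest_window_min, anchor_touches = anchor_touches,
    nocturnal_touch_model = nocturnal_touch_model,
    nonwear_episodes = nonwear_episodes,
    light_day = light_day, light_night = light_night,
    temp_wear = temp_wear, temp_nonwear = temp_nonwear,
    diary_noise_min = diary_noise_min, seed = as.integer(seed)
  ), class = "subject_scenario")
}

# Homogeneous Poisson events on [a, b) (numeric seconds), rate per hour.
rpois_interval <- function(rate_per_h, a, b) {
  len_h <- (b - a) / 3600
  if (len_h <= 0 || rate_per_h <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_per_h * len_h)
  sort(stats::runif(n, a, b))
}

# Inhomogeneous Poisson by thinning; lambda_h(t) gives the rate (per hour)
# at numeric-second times t and must be bounded by rate_max.
rpois_inhom <- function(rate_max, a, b, lambda_h) {
  cand <- rpois_interval(rate_max, a, b)
  if (length(cand) == 0) return(cand)
  keep <- stats::runif(length(cand)) < lambda_h(cand) / rate_max
  cand[keep]
}

# Stage 1: everything except the raw acceleration streams, drawn in a fixed
# order from the scenario seed.
sim_ground_truth <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  cycles <- sc$start_date + seq_len(sc$n_days) - 1
  jit_o <- pmax(-120, pmin(120, stats::rnorm(sc$n_days, 0, sc$jitter_sd_min))) * 60
  jit_w <- pmax(-120, pmin(120, stats::rnorm(sc$n_days, 0, sc$jitter_sd_min))) * 60
  onset <- local_datetime(cycles, sc$onset_h) + jit_o
  wake <- local_datetime(cycles + 1, sc$wake_h) + jit_w
  span_start <- cycle_noon(cycles[1])
  span_end <- cycle_noon(cycles[sc$n_days]) + 86400

  o_num <- as.numeric(onset); w_num <- as.numeric(wake)
  wake_iv_start <- c(as.numeric(span_start), w_num)
  wake_iv_end <- c(o_num, as.numeric(span_end))

  touches <- numeric(0)
  for (i in seq_along(wake_iv_start)) {
    a <- wake_iv_start[i]; b <- wake_iv_end[i]
    touches <- c(touches, rpois_interval(sc$touch_rate_day, a, b))
    boost <- (sc$rest_boost - 1) * sc$touch_rate_day
    if (boost > 0) {
      rw <- sc$rest_window_min * 60
      if (i <= sc$n_days) {               # pre-bed rest before onset i
        touches <- c(touches, rpois_interval(boost, max(a, b - rw), b))
      }
      if (i >= 2) {                       # post-wake rest after wake i-1
        touches <- c(touches, rpois_interval(boost, a, min(b, a + rw)))
      }
    }
  }
  if (sc$anchor_touches) {
    touches <- c(touches, o_num - 1, w_num + 1)
  }

  noct_list <- vector("list", sc$n_days)
  for (i in seq_len(sc$n_days)) {
    ev <- numeric(0)
    for (mod in sc$nocturnal_touch_model) {
      ev <- c(ev, switch(
        mod$type,
        none = numeric(0),
        post_onset_decay = {
          dur_s <- mod$duration * 3600
          end <- min(o_num[i] + dur_s, w_num[i])
          rpois_inhom(mod$rate, o_num[i], end,
                      function(t) mod$rate * pmax(0, 1 - (t - o_num[i]) / dur_s))
        },
        pre_wake_ramp = {
          dur_s <- mod$duration * 3600
          beg <- max(w_num[i] - dur_s, o_num[i])
          rpois_inhom(mod$rate, beg, w_num[i],
                      function(t) mod$rate * pmax(0, 1 - (w_num[i] - t) / dur_s))
        },
        hourly_checks = {
          iv <- (mod$interval_h %||% 1) * 3600
          burst <- mod$burst %||% 1
          at <- seq(o_num[i] + iv, w_num[i] - 600, by = iv)
          if (length(at) == 0) numeric(0) else {
            rep(at, each = burst) + stats::runif(length(at) * burst, 0, 30)
          }
        },
        abort(sprintf("unknown nocturnal touch model '%s'", mod$type),
              class = "tapsleep_scenario_error")
      ))
    }
    ev <- ev[ev > o_num[i] & ev < w_num[i]]
    noct_list[[i]] <- sort(ev)
  }
  noct <- tibble::tibble(
    night_id = rep(cycles, lengths(noct_list)),
    time = as_local_time(unlist(noct_list) %||% numeric(0))
  )
  touches <- sort(c(touches, as.numeric(noct$time)))
  log <- new_touch_log(touches)

  d_err_s <- stats::rnorm(sc$n_days, 0, sc$diary_noise_min) * 60
  d_err_w <- stats::rnorm(sc$n_days, 0, sc$diary_noise_min) * 60
  diary <- tibble::tibble(
    date = cycles + 1,
    report_time = wake + 1800,
    sleep_time = clock_hours_of(onset + d_err_s),
    wake_time = clock_hours_of(wake + d_err_w)
  )

  truth_nights <- tibble::tibble(
    night_id = cycles, onset = onset, wake = wake,
    last_touch_before_sleep = as_local_time(
      if (sc$anchor_touches) o_num - 1 else
        vapply(o_num, function(o) {
          prior <- touches[touches < o]
          if (length(prior)) max(prior) else NA_real_
        }, numeric(1))),
    first_touch_after_wake = as_local_time(
      if (sc$anchor_touches) w_num + 1 else
        vapply(w_num, function(w) {
          post <- touches[touches >= w]
          if (length(post)) min(post) else NA_real_
        }, numeric(1))),
    n_nocturnal = lengths(noct_list)
  )
  list(nights = truth_nights, touches = log, diary = diary,
       nocturnal_touches = noct,
       span = c(span_start, as_local_time(span_end)))
}

# Stage 2: raw actigraphy for one noon-to-noon cycle, rendered from a
# per-day derived seed so any contiguous subset of days is byte-identical
# to the same days of a full rendering.
render_day <- function(scenario, truth, day) {
  sc <- scenario
  set.seed((sc$seed %% 100000L) * 20011L + day * 7919L)
  rate <- sc$sample_rate
  noon <- as.numeric(cycle_noon(truth$nights$night_id[day]))
  n <- 86400L * rate
  spm <- 60L * rate

  min_t <- noon + (0:1439) * 60 + 30            # minute centers
  o <- as.numeric(truth$nights$onset[day])
  w <- as.numeric(truth$nights$wake[day])
  tau <- sc$transition_min * 60 / (2 * log(99)) # 1%-99% span = transition_min
  f_sleep <- stats::plogis((min_t - o) / tau) * stats::plogis((w - min_t) / tau)

  peak_h <- (sc$wake_h + sc$onset_h) / 2                     # mid-wake clock
  circ <- 1 + sc$circadian_mod * cos(2 * pi * (min_t / 3600 - peak_h) / 24)
  sd_min <- sc$sleep_noise_g + (sc$day_noise_g * circ - sc$sleep_noise_g) *
    (1 - f_sleep)
  light_min <- ifelse(f_sleep > 0.5, sc$light_night, sc$light_day)
  temp_min <- rep(sc$temp_wear, 1440)

  ne <- sc$nonwear_episodes
  if (!is.null(ne)) {
    ne <- ne[ne$day == day, , drop = FALSE]
    for (k in seq_len(nrow(ne))) {
      a <- noon + ((ne$start_clock_h[k] - 12) %% 24) * 3600
      b <- a + ne$duration_h[k] * 3600
      hit <- min_t >= a & min_t < b
      sd_min[hit] <- 2e-4                        # device resting on a table
      temp_min[hit] <- sc$temp_nonwear
    }
  }

  sd_s <- rep(sd_min, each = spm)
  ax <- stats::rnorm(n) * sd_s
  ay <- stats::rnorm(n) * sd_s
  az <- 1 + stats::rnorm(n) * sd_s
  new_actigraphy_recording(
    time = noon + (0:(n - 1L)) / rate,
    ax = ax, ay = ay, az = az,
    light = rep(light_min, each = spm),
    temperature = rep(temp_min, each = spm),
    sample_rate = rate
  )
}

render_actigraphy_days <- function(scenario, truth, days) {
  parts <- lapply(days, function(d) render_day(scenario, truth, d))
  rec <- dplyr::bind_rows(parts)
  attr(rec, "sample_rate") <- scenario$sample_rate
  attr(rec, "missing_intervals") <- tibble::tibble(
    start = as_local_time(numeric(0)), end = as_local_time(numeric(0)))
  class(rec) <- c("actigraphy_recording", class(rec))
  rec
}

#' Simulate one subject's actigraphy, touch-log and diary streams
#'
#' Deterministic from the scenario seed: the nightly ground truth, touch
#' process and diary are drawn first; each day's raw acceleration, light
#' and temperature streams are then rendered from a seed derived from
#' (scenario seed, day), so rendering a subset of days reproduces exactly
#' the corresponding days of the full rendering.  Wrist motility follows a
#' day/night two-level profile with logistic transitions at the true onset
#' and wake plus a 24-h cosinor modulation; touches form a piecewise
#' constant-rate Poisson process confined to wake (elevated in the wakeful
#' rest windows around the night), plus the nocturnal model's events.  No
#' touch ever falls strictly inside a sleep window unless placed by the
#' nocturnal model.
#'
#' @param scenario a [subject_scenario()].
#' @param days integer vector of cycle indices to render actigraphy for
#'   (default all); `integer(0)` skips the raw streams.
#' @return a list with elements `recording` (an `actigraphy_recording`, or
#'   `NULL` if `days` is empty), `touches` (a `touch_log`), `diary`, and
#'   `truth` (list: `nights`, `nocturnal_touches`, `span`).
#' @export
simulate_subject <- function(scenario, days = NULL) {
  gt <- sim_ground_truth(scenario)
  days <- days %||% seq_len(scenario$n_days)
  rec <- if (length(days) == 0) NULL else
    render_actigraphy_days(scenario, gt, days)
  list(recording = rec, touches = gt$touches, diary = gt$diary,
       truth = gt[c("nights", "nocturnal_touches", "span")])
}

#' Run both sleep pipelines on a simulated subject, memory-efficiently
#'
#' Renders the raw actigraphy in noon-to-noon chunks, reduces each chunk to
#' its per-minute activity series immediately, then runs the complete
#' actigraphy pipeline on the merged minute grid and the tappigraphy
#' pipeline on the full touch log.
#'
#' @param scenario a [subject_scenario()].
#' @param config a [tapsleep_config()].
#' @param chunk_days days of raw signal held in memory at once, default 4.
#' @return a list with `truth`, `touches`, `diary`, `act` (the
#'   `tapsleep_actigraphy` result), `tap` (the `tapsleep_tappigraphy`
#'   result), and the two night tables `act_nights`, `tap_nights`.
#' @export
score_scenario <- function(scenario, config = tapsleep_config(),
                           chunk_days = 4) {
  gt <- sim_ground_truth(scenario)
  day_chunks <- split(seq_len(scenario$n_days),
                      ceiling(seq_len(scenario$n_days) / chunk_days))
  activity <- NULL
  for (ch in day_chunks) {
    rec <- render_actigraphy_days(scenario, gt, ch)
    act_part <- compute_activity(rec, cutoff_hz = config$activity.cutoff_hz)
    rm(rec)
    activity <- if (is.null(activity)) act_part else
      dplyr::bind_rows(activity, act_part)
  }
  class(activity) <- c("activity_series", class(tibble::tibble()))
  act <- actigraphy_sleep(NULL, config, activity = activity)
  tap <- tappigraphy_sleep(gt$touches, config)
  list(truth = gt[c("nights", "nocturnal_touches", "span")],
       touches = gt$touches, diary = gt$diary,
       act = act, tap = tap,
       act_nights = act$nights, tap_nights = tap$nights)
}
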