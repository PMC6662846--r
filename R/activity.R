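# Zero-phase low-pass: Butterworth coefficients from signal::butter applied
# forward then backward through stats::filter (C recursive core).  Matches
# signal::filter exactly on each pass; the double pass cancels phase delay.
zero_phase_lowpass <- function(x, sample_rate, cutoff_hz = 2, order = 4) {
  if (sample_rate <= 2 * cutoff_hz) {
    abort(sprintf("sample rate %.3g Hz cannot realize a %.3g Hz low-pass (need rate > 2 x cutoff)",
                  sample_rate, cutoff_hz),
          class = "tapsleep_config_error")
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  # The filter has unit DC gain, so running it on x - x[1] and adding x[1]
  # back removes the step transient a zero-initial-condition pass would
  # produce at the edges (a constant input maps to itself exactly).
  one_pass <- function(b, a, x) {
    x0 <- x[1]
    x <- x - x0
    nb <- length(b)
    fir <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
    for (i in seq_len(nb - 1)) fir[i] <- sum(b[1:i] * x[i:1])
    as.numeric(stats::filter(fir, -a[-1], method = "recursive")) + x0
  }
  rev(one_pass(bf$b, bf$a, rev(one_pass(bf$b, bf$a, x))))
}

new_activity_series <- function(minute, counts, missing,
                                light_median = NA_real_,
                                temp_median = NA_real_) {
  out <- tibble::tibble(
    minute = as_local_time(minute),
    counts = counts, missing = missing,
    light_median = light_median, temp_median = temp_median
  )
  class(out) <- c("activity_series", class(out))
  out
}

#' Per-minute activity counts from raw acceleration
#'
#' The tri-axial acceleration is combined with the sum of squares
#' (`m = ax^2 + ay^2 + az^2`, in g^2), low-pass filtered at `cutoff_hz` with
#' a zero-phase Butterworth filter, baseline-removed by subtracting the
#' within-minute median (the local static-gravity/posture level), rectified,
#' and summed within each clock minute.  Minutes overlapping recorded
#' missing-data intervals, and incomplete head/tail minutes, are masked.
#' Per-minute medians of ambient light and near-body temperature are
#' carried along for the veto steps.
#'
#' @param recording an `actigraphy_recording` (sample rate of at least 5 Hz,
#'   duration of at least one full clock minute).
#' @param cutoff_hz low-pass cutoff, default 2 Hz.
#' @param order Butterworth order, default 4.
#' @return a tibble of class `activity_series` with columns `minute`,
#'   `counts`, `missing`, `light_median`, `temp_median` on a uniform 60-s
#'   grid aligned to clock minutes.
#' @export
compute_activity <- function(recording, cutoff_hz = 2, order = 4) {
  rate <- attr(recording, "sample_rate")
  if (is.null(rate) || rate < 5) {
    abort("compute_activity requires a recording with sample_rate >= 5 Hz",
          class = "tapsleep_config_error")
  }
  t <- as.numeric(recording$time)
  first_minute <- ceiling(t[1] / 60)
  last_minute <- floor((t[length(t)] + 1 / rate) / 60)
  if (last_minute - first_minute < 1) {
    abort("recording must cover at least one full clock minute",
          class = "tapsleep_value_error")
  }
  m <- recording$ax^2 + recording$ay^2 + recording$az^2
  filt <- zero_phase_lowpass(m, rate, cutoff_hz, order)

  minute_idx <- floor(t / 60) - first_minute   # 0-based; head partial -> -1
  n_min <- last_minute - first_minute
  keep <- minute_idx >= 0 & minute_idx < n_min
  mi <- minute_idx[keep] + 1L                  # sorted, so groups contiguous
  n_per <- tabulate(mi, nbins = n_min)
  g_end <- cumsum(n_per)
  g_start <- g_end - n_per + 1L

  per_minute <- function(x, f) {
    xk <- x[keep]
    vapply(seq_len(n_min), function(i) {
      if (n_per[i] == 0L) NA_real_ else f(xk[g_start[i]:g_end[i]])
    }, numeric(1))
  }
  counts <- per_minute(filt, function(v) sum(abs(v - median(v))))
  light_med <- per_minute(recording$light, median)
  temp_med <- per_minute(recording$temperature, median)

  minute <- as_local_time((first_minute + 0:(n_min - 1)) * 60)
  spm <- round(60 * rate)
  missing <- n_per < spm
  mi <- attr(recording, "missing_intervals")
  if (!is.null(mi) && nrow(mi) > 0) {
    for (k in seq_len(nrow(mi))) {
      hit <- minute < mi$end[k] & (minute + 60) > mi$start[k]
      missing <- missing | hit
    }
  }
  counts[missing] <- NA_real_
  new_activity_series(minute, counts, missing,
                      as.numeric(light_med), as.numeric(temp_med))
}

#' Published one-minute-epoch Cole-Kripke weights
#'
#' The 1992 one-minute-epoch weight set for the minute window spanning lags
#' -4 ... +2 around the scored minute, with its scale factor.
#'
#' @return a list with elements `weights` (length 7, lags -4..+2) and
#'   `scale`.
#' @export
ck_weights <- function() {
  list(weights = c(404, 598, 326, 441, 1408, 508, 350), scale = 1e-5)
}

new_d_series <- function(minute, d, weights, scale) {
  out <- tibble::tibble(minute = as_local_time(minute), d = d)
  attr(out, "weights") <- weights
  attr(out, "scale") <- scale
  class(out) <- c("d_series", class(out))
  out
}

#' Cole-Kripke D score per minute
#'
#' `D_t = scale * sum_{k=-4}^{+2} w_k * A_{t+k}`: the weighted sum of the
#' activity count at minute t and its surrounding minutes.  D is undefined
#' (NA) where the 7-minute window is incomplete — the first 4 and last 2
#' minutes of the grid, and any minute whose window touches a masked minute.
#'
#' @param activity an `activity_series` on a uniform minute grid.
#' @param weights numeric length 7 (lags -4..+2); defaults to the published
#'   one-minute-epoch set, see [ck_weights()].
#' @param scale scalar multiplier, default `1e-5`.
#' @return a tibble of class `d_series` with columns `minute`, `d`.
#' @export
cole_kripke_d <- function(activity, weights = ck_weights()$weights,
                          scale = ck_weights()$scale) {
  if (length(weights) != 7) {
    abort("cole_kripke_d requires exactly 7 weights (lags -4..+2)",
          class = "tapsleep_config_error")
  }
  a <- activity$counts
  n <- length(a)
  d <- rep(NA_real_, n)
  if (n >= 7) {
    acc <- numeric(n - 6)
    for (j in 0:6) {                       # lag k = j - 4
      acc <- acc + weights[j + 1] * a[(1 + j):(n - 6 + j)]
    }
    d[5:(n - 2)] <- scale * acc
  }
  new_d_series(activity$minute, d, weights, scale)
}

#' Score each minute as sleep or wake
#'
#' A minute is scored sleep iff `D < threshold` (strict); minutes with
#' undefined D are scored unknown (`NA`).
#'
#' @param d a `d_series`.
#' @param threshold sleep threshold on D, default 1.
#' @return a tibble with columns `minute` and `asleep` (logical, `NA` where
#'   D is undefined).
#' @export
score_sleep_wake <- function(d, threshold = 1) {
  tibble::tibble(minute = d$minute, asleep = d$d < threshold)
}
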