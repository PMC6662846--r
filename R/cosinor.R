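#' Fit a fixed-period 24-h cosinor to a time series
#'
#' Ordinary least squares on `y = M + b1*cos(wt) + b2*sin(wt)` with
#' `w = 2*pi/period`.  The mesor M is the rhythm-adjusted mean, the
#' amplitude `A = sqrt(b1^2 + b2^2)` and the acrophase
#' `phi = atan2(b2, b1) * period/(2*pi) mod period` is the clock time of
#' the fitted peak (time measured as local hours of day).
#'
#' @param data a data frame with a `time` column (POSIXct) and a `value`
#'   column (activity counts, touch counts, ...).
#' @param period fixed period in hours, default 24.
#' @param min_span_h minimum required data span in hours (defaults to one
#'   full period; the per-cycle fitting mode relaxes it slightly because a
#'   single noon-to-noon cycle spans one bin less than 24 h).
#' @return an object of class `cosinor_fit`: a list with `mesor`,
#'   `amplitude`, `acrophase_h`, `period_h`, `coefficients`, `r_squared`,
#'   `n`, `residual_sd` and the fitting `data`.
#' @export
cosinor_fit <- function(data, period = 24, min_span_h = period) {
  t_h <- as.numeric(data$time) / 3600
  y <- data$value
  ok <- !is.na(t_h) & !is.na(y)
  t_h <- t_h[ok]; y <- y[ok]
  if (length(t_h) < 3 || length(unique(t_h)) < 3) {
    abort("cosinor_fit needs at least 3 distinct time points",
          class = "tapsleep_data_error")
  }
  if (diff(range(t_h)) < min_span_h) {
    abort(sprintf("cosinor_fit needs at least %g h of data (got %.2f h)",
                  min_span_h, diff(range(t_h))),
          class = "tapsleep_data_error")
  }
  w <- 2 * pi / period
  cw <- cos(w * t_h); sw <- sin(w * t_h)
  fit <- lm(y ~ cw + sw)
  b <- coef(fit)
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  acrophase <- (atan2(b[3], b[2]) * period / (2 * pi)) %% period
  res <- fit$residuals
  r2 <- if (sd(y) == 0) 0 else 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(
    mesor = unname(b[1]), amplitude = unname(amplitude),
    acrophase_h = unname(acrophase), period_h = period,
    coefficients = c(mesor = unname(b[1]), beta_cos = unname(b[2]),
                     beta_sin = unname(b[3])),
    r_squared = r2, n = length(y), residual_sd = sd(res),
    data = tibble::tibble(time = as_local_time(t_h * 3600), value = y)
  ), class = "cosinor_fit")
}

#' Evaluate the fitted sinusoid
#' @param fit a `cosinor_fit`.
#' @param t POSIXct times or numeric hours.
#' @return fitted values `M + A*cos(2*pi*(t - phi)/period)`.
#' @export
cosinor_predict <- function(fit, t) {
  t_h <- if (inherits(t, "POSIXct")) as.numeric(t) / 3600 else as.numeric(t)
  fit$mesor + fit$amplitude *
    cos(2 * pi * (t_h - fit$acrophase_h) / fit$period_h)
}

#' Per-cycle 6-h circadian low-activity windows
#'
#' The window is centered on the bathyphase of the fitted sinusoid — the
#' clock time of its minimum, `acrophase + 12 h mod 24` — which for a pure
#' sinusoid is the 6-h window with the least fitted activity.  One window
#' is instantiated per noon-to-noon cycle, its center placed at the
#' bathyphase clock time falling inside that cycle.
#'
#' @param fit a `cosinor_fit` with non-zero amplitude.
#' @param cycles Date vector of cycle ids (the date of the starting noon).
#' @param length_h window length in hours, default 6.
#' @return a tibble with columns `cycle`, `start`, `end`.
#' @export
low_activity_windows <- function(fit, cycles, length_h = 6) {
  if (fit$amplitude <= 1e-9 * max(1, abs(fit$mesor))) {
    abort("cosinor amplitude is zero: no rhythm; low-activity window undefined",
          class = "tapsleep_data_error")
  }
  bathy <- (fit$acrophase_h + fit$period_h / 2) %% 24
  cycles <- as.Date(cycles)
  center <- cycle_noon(cycles) + round(((bathy - 12) %% 24) * 3600, 3)
  tibble::tibble(cycle = cycles,
                 start = center - length_h / 2 * 3600,
                 end = center + length_h / 2 * 3600)
}

#' Per-cycle 6-h low-activity windows from per-cycle cosinor fits
#'
#' Alternative to the default global fit: the sinusoid is refit on each
#' noon-to-noon cycle's own data and the bathyphase-centered window is
#' derived per cycle.  Cycles whose fit fails (too little data, no
#' rhythm) are skipped with a warning.  Noisier than the global fit;
#' exposed for sensitivity analysis via the `cosinor.per_cycle`
#' configuration flag.
#'
#' @param data a data frame with `time` and `value` columns.
#' @param cycles Date vector of cycle ids.
#' @param length_h window length in hours, default 6.
#' @return a tibble with columns `cycle`, `start`, `end` (possibly fewer
#'   rows than `cycles`).
#' @export
per_cycle_low_windows <- function(data, cycles, length_h = 6) {
  cycles <- as.Date(cycles)
  out <- purrr::map_dfr(cycles, function(cy) {
    noon <- cycle_noon(cy)
    sub <- data[data$time >= noon & data$time < noon + 86400, , drop = FALSE]
    fit <- tryCatch(cosinor_fit(sub, min_span_h = 20),
                    tapsleep_data_error = function(e) NULL)
    if (is.null(fit) || fit$amplitude <= 1e-9 * max(1, abs(fit$mesor))) {
      return(tibble::tibble())
    }
    low_activity_windows(fit, cy, length_h)
  })
  skipped <- setdiff(cycles, out$cycle)
  if (length(skipped) > 0) {
    warn(sprintf("per-cycle cosinor fit failed for %d cycle(s); no low-activity window there",
                 length(skipped)))
  }
  out
}

#' Hourly touch counts for the tappigraphy cosinor fit
#' @param log a `touch_log`.
#' @param bin_minutes bin width in minutes, default 60.
#' @return a tibble with `time` (bin start) and `value` (touch count).
#' @export
touch_count_series <- function(log, bin_minutes = 60) {
  if (nrow(log) == 0) {
    abort("cannot bin an empty touch log", class = "tapsleep_data_error")
  }
  bin_s <- bin_minutes * 60
  t <- as.numeric(log$time)
  first <- floor(t[1] / bin_s)
  last <- floor(t[length(t)] / bin_s)
  idx <- floor(t / bin_s) - first
  counts <- tabulate(idx + 1L, nbins = last - first + 1L)
  tibble::tibble(time = as_local_time((first + seq_along(counts) - 1) * bin_s),
                 value = as.numeric(counts))
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("24-h cosinor fit\n")
  cat(sprintf("  mesor: %.4g   amplitude: %.4g   acrophase: %.2f h   (n = %d, R^2 = %.3f)\n",
              x$mesor, x$amplitude, x$acrophase_h, x$n, x$r_squared))
  invisible(x)
}
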