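#' Linearize the 24-h clock across midnight
#'
#' Sleep landmarks cluster around midnight, so raw clock values are not
#' linearly comparable (23.5 h vs 0.5 h).  Clock times strictly before the
#' cutoff (10:00 by default) are shifted by +24 h, so 01:00 past midnight
#' becomes 25 h; times at or after the cutoff are unchanged.  The map is
#' injective on a full day and order-preserving along a night.
#'
#' @param t clock times: POSIXct (the time-of-day part is used), numeric
#'   fractional hours, or "HH:MM" strings.
#' @param cutoff_h clock hour below which the shift applies, default 10.
#' @return numeric hours in `[cutoff_h, cutoff_h + 24)`.
#' @export
linearize_clock <- function(t, cutoff_h = 10) {
  h <- if (inherits(t, "POSIXct")) clock_hours_of(t) else parse_clock(t)
  h + 24 * (h < cutoff_h)
}

#' Sleep fracture fraction
#'
#' For each actigraphy-derived sleep window, the touchscreen touches falling
#' strictly inside `(onset, wake)` split the window into sub-intervals; the
#' SFF is the longest sub-interval divided by the window duration.  SFF = 1
#' means smartphone-uninterrupted sleep; SFF = 0.5 means the longest
#' continuous sleep covered only half the window.
#'
#' @param nights a [night_table()] (or any tibble with `night_id`, `onset`,
#'   `wake`).
#' @param touches a `touch_log` covering the windows' spans.
#' @return a tibble with columns `night_id`, `sff`,
#'   `n_interrupting_touches`.
#' @export
sleep_fracture_fraction <- function(nights, touches) {
  if (any(nights$wake <= nights$onset)) {
    abort("sleep_fracture_fraction requires windows of positive duration",
          class = "tapsleep_value_error")
  }
  tt <- as.numeric(touches$time)
  purrr::map_dfr(seq_len(nrow(nights)), function(i) {
    o <- as.numeric(nights$onset[i]); w <- as.numeric(nights$wake[i])
    inside <- tt[tt > o & tt < w]
    seg <- diff(c(o, sort(inside), w))
    tibble::tibble(night_id = nights$night_id[i],
                   sff = max(seg) / (w - o),
                   n_interrupting_touches = length(inside))
  })
}

#' Touch probability by physical-activity level
#'
#' For every minute with a defined D score, the minute either contains a
#' touch or not.  Minutes are grouped into D bins of width `step` up to
#' `cap`, plus one overflow bin for D >= `cap` (high physical activity);
#' the per-bin value is the fraction of the bin's minutes containing at
#' least one touch.
#'
#' @param d a `d_series`.
#' @param touches a `touch_log` time-aligned with the D grid.
#' @param step bin width in D units, default 0.25.
#' @param cap lower edge of the overflow bin, default 7.
#' @return a tibble with columns `bin_lo`, `bin_hi`, `n_minutes`,
#'   `p_touch`.
#' @export
touch_by_d_histogram <- function(d, touches, step = 0.25, cap = 7) {
  ok <- !is.na(d$d)
  dv <- d$d[ok]
  minute_key <- floor(as.numeric(d$minute[ok]) / 60)
  touched_minutes <- unique(floor(as.numeric(touches$time) / 60))
  has_touch <- minute_key %in% touched_minutes
  n_bins <- as.integer(round(cap / step))
  bin <- pmin(floor(dv / step), n_bins)      # overflow bin D >= cap
  lo <- c(seq(0, cap - step, by = step), cap)
  hi <- c(seq(step, cap, by = step), Inf)
  n_minutes <- tabulate(bin + 1L, nbins = n_bins + 1L)
  n_touched <- tabulate(bin[has_touch] + 1L, nbins = n_bins + 1L)
  tibble::tibble(bin_lo = lo, bin_hi = hi, n_minutes = n_minutes,
                 p_touch = ifelse(n_minutes > 0, n_touched / n_minutes, 0))
}

#' Peri-sleep touch-probability profile
#'
#' For each subject and each 3-min bin measured from the anchor (after
#' sleep onset, or before wake-up), the fraction of that subject's nights
#' containing at least one touch in the bin.  Population mean and SD are
#' taken across subjects and each bin is tested against 0 with a one-sample
#' t-test, Bonferroni-corrected over the number of bins.  Bins extending
#' beyond a night's duration are excluded for that night (per-bin n
#' bookkeeping).
#'
#' @param nights a tibble with columns `subject`, `onset`, `wake` (one row
#'   per night).
#' @param touches a tibble with columns `subject`, `time` (all touch
#'   events, any state).
#' @param anchor `"onset"` (bins measured forward from sleep onset) or
#'   `"wake"` (bins measured backward from wake-up).
#' @param bin_min bin width in minutes, default 3.
#' @param horizon_min profile depth in minutes, default 240.
#' @param alpha familywise significance level before Bonferroni correction,
#'   default 0.05.
#' @return a tibble of class `peri_sleep_profile` with columns
#'   `bin_offset_min` (bin start offset from the anchor, signed), `mean_p`,
#'   `sd_p`, `n_subjects`, `t`, `p_value`, `significant`; the per-subject
#'   probability matrix is kept in attribute `subject_probs`.
#' @export
peri_sleep_profile <- function(nights, touches, anchor = c("onset", "wake"),
                               bin_min = 3, horizon_min = 240,
                               alpha = 0.05) {
  anchor <- match.arg(anchor)
  n_bins <- floor(horizon_min / bin_min)
  subjects <- unique(nights$subject)
  touch_by_subj <- split(as.numeric(touches$time), touches$subject)

  probs <- matrix(NA_real_, nrow = length(subjects), ncol = n_bins,
                  dimnames = list(as.character(subjects), NULL))
  for (si in seq_along(subjects)) {
    nw <- nights[nights$subject == subjects[si], , drop = FALSE]
    tt <- touch_by_subj[[as.character(subjects[si])]] %||% numeric(0)
    hit <- matrix(NA, nrow = nrow(nw), ncol = n_bins)
    for (ni in seq_len(nrow(nw))) {
      o <- as.numeric(nw$onset[ni]); w <- as.numeric(nw$wake[ni])
      dur_min <- (w - o) / 60
      usable <- floor(dur_min / bin_min)
      k <- seq_len(min(n_bins, usable))
      if (length(k) == 0) next
      if (anchor == "onset") {
        lo <- o + (k - 1) * bin_min * 60
      } else {
        lo <- w - k * bin_min * 60
      }
      hi <- lo + bin_min * 60
      inside <- tt[tt >= min(lo) & tt < max(hi)]
      hit[ni, k] <- vapply(seq_along(k), function(j) {
        any(inside >= lo[j] & inside < hi[j])
      }, logical(1))
    }
    probs[si, ] <- colMeans(hit, na.rm = TRUE)
  }
  probs[is.nan(probs)] <- NA_real_

  alpha_adj <- alpha / n_bins
  res <- purrr::map_dfr(seq_len(n_bins), function(b) {
    v <- probs[, b]
    v <- v[!is.na(v)]
    n_s <- length(v)
    if (n_s == 0) {
      return(tibble::tibble(mean_p = NA_real_, sd_p = NA_real_,
                            n_subjects = 0L, t = NA_real_, p_value = NA_real_))
    }
    m <- mean(v); s <- if (n_s > 1) sd(v) else NA_real_
    if (n_s < 2 || is.na(s)) {
      tv <- NA_real_; pv <- NA_real_
    } else if (s == 0) {
      tv <- if (m == 0) 0 else Inf
      pv <- if (m == 0) 1 else 0
    } else {
      tt <- t.test(v, mu = 0)
      tv <- unname(tt$statistic); pv <- tt$p.value
    }
    tibble::tibble(mean_p = m, sd_p = s, n_subjects = n_s,
                   t = tv, p_value = pv)
  })
  offsets <- if (anchor == "onset") {
    (seq_len(n_bins) - 1) * bin_min
  } else {
    -(seq_len(n_bins)) * bin_min
  }
  out <- tibble::tibble(bin_offset_min = offsets, res)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha_adj
  attr(out, "subject_probs") <- probs
  attr(out, "anchor") <- anchor
  attr(out, "alpha_adjusted") <- alpha_adj
  class(out) <- c("peri_sleep_profile", class(out))
  out
}

#' Pair nights from two estimation sources
#'
#' Rows are matched by noon-to-noon cycle (`night_id`); unmatched nights
#' are dropped and counted.  Onsets and wakes are linearized with
#' [linearize_clock()] so values straddling midnight stay comparable.
#'
#' @param nights_x,nights_y [night_table()]s for the same subject.
#' @param cutoff_h linearization cutoff, default 10.
#' @return a tibble with columns `night_id`, `x_source`, `y_source`,
#'   `onset_x`, `onset_y`, `wake_x`, `wake_y` (linearized hours),
#'   `duration_x`, `duration_y` (hours) and `pct_error`
#'   (`100 * (duration_y - duration_x) / duration_x`); the number of
#'   unmatched nights is in attribute `n_dropped`.
#' @export
pair_nights <- function(nights_x, nights_y, cutoff_h = 10) {
  j <- dplyr::inner_join(
    tibble::as_tibble(nights_x)[, c("night_id", "source", "onset", "wake", "duration_h")],
    tibble::as_tibble(nights_y)[, c("night_id", "source", "onset", "wake", "duration_h")],
    by = "night_id", suffix = c("_x", "_y")
  )
  out <- tibble::tibble(
    night_id = j$night_id,
    x_source = j$source_x, y_source = j$source_y,
    onset_x = linearize_clock(j$onset_x, cutoff_h),
    onset_y = linearize_clock(j$onset_y, cutoff_h),
    wake_x = linearize_clock(j$wake_x, cutoff_h),
    wake_y = linearize_clock(j$wake_y, cutoff_h),
    duration_x = j$duration_h_x, duration_y = j$duration_h_y,
    pct_error = 100 * (j$duration_h_y - j$duration_h_x) / j$duration_h_x
  )
  attr(out, "n_dropped") <- (nrow(nights_x) - nrow(j)) + (nrow(nights_y) - nrow(j))
  out
}

#' Robust simple regression (bisquare IRLS)
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685), the standard robust alternative to ordinary
#' least squares when a small fraction of nights are gross outliers.
#' R-squared is computed on the weighted fit.
#'
#' @param data a data frame.
#' @param formula a two-sided formula with a single predictor,
#'   e.g. `y ~ x`.
#' @return an object of class `robust_fit`: a list with `beta`,
#'   `intercept`, `r_squared`, `t`, `dof`, `p`, `n` and the underlying
#'   `rlm` fit.
#' @export
robust_fit <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2) {
    abort("robust_fit expects a simple regression: y ~ x",
          class = "tapsleep_config_error")
  }
  y <- mf[[1]]; x <- mf[[2]]
  if (length(y) < 3) {
    abort("robust_fit needs at least 3 paired points",
          class = "tapsleep_data_error")
  }
  if (sd(x) == 0) {
    abort("robust_fit: predictor has zero variance",
          class = "tapsleep_data_error")
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  b <- coef(fit)
  w <- fit$w
  yhat <- fit$fitted.values
  ybar_w <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar_w)^2)
  dof <- length(y) - 2
  tval <- summary(fit)$coefficients["x", "t value"]
  structure(list(beta = unname(b["x"]), intercept = unname(b["(Intercept)"]),
                 r_squared = r2, t = tval, dof = dof,
                 p = 2 * pt(-abs(tval), dof), n = length(y), rlm = fit),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("bisquare robust fit: beta = %.4g, intercept = %.4g, R^2 = %.3f, t(%d) = %.2f, p = %.3g\n",
              x$beta, x$intercept, x$r_squared, x$dof, x$t, x$p))
  invisible(x)
}

#' Per-subject summary of nightly sleep estimates
#'
#' Medians of linearized onset and wake clock times, median duration, and
#' the coefficient of variation of duration (sample SD / mean, the
#' intra-individual regularity measure).  If a reference night table is
#' supplied, nights are paired by cycle and the median (and median
#' absolute) percentage duration error versus the reference is added.
#'
#' @param nights a [night_table()] for one subject.
#' @param reference optional [night_table()] used as ground truth for error
#'   metrics.
#' @param cutoff_h linearization cutoff, default 10.
#' @return a one-row tibble with `n_nights`, `median_onset`, `median_wake`,
#'   `median_duration`, `cov`, and (given a reference) `median_pct_error`,
#'   `median_abs_pct_error`, `n_paired`.
#' @export
subject_summary <- function(nights, reference = NULL, cutoff_h = 10) {
  dur <- nights$duration_h
  cov <- if (length(dur) >= 2) sd(dur) / mean(dur) else NA_real_
  out <- tibble::tibble(
    n_nights = nrow(nights),
    median_onset = median(linearize_clock(nights$onset, cutoff_h)),
    median_wake = median(linearize_clock(nights$wake, cutoff_h)),
    median_duration = median(dur),
    cov = cov
  )
  if (!is.null(reference)) {
    pairs <- pair_nights(reference, nights, cutoff_h)
    out$median_pct_error <- median(pairs$pct_error)
    out$median_abs_pct_error <- median(abs(pairs$pct_error))
    out$n_paired <- nrow(pairs)
  }
  out
}

#' Multiple regression with Bonferroni-corrected coefficient tests
#'
#' Ordinary multiple regression of a sleep measure on a set of covariates
#' (canonically touches/day, age, gender, height, weight).  All non-
#' intercept coefficients are tested simultaneously, so the per-test alpha
#' is Bonferroni-corrected by their number (0.05/5 = 0.01 for the canonical
#' five hypotheses).  A condition-number warning is issued for collinear
#' covariates.
#'
#' @param data a data frame with complete covariate rows.
#' @param formula model formula, e.g.
#'   `duration ~ touches_per_day + age + gender + height + weight`.
#' @param alpha familywise level before correction, default 0.05.
#' @return an object of class `multi_fit`: a list with `coefficients`
#'   (tibble: term, estimate, t, p, significant), `r_squared`,
#'   `f_statistic`, `f_dof`, `f_p`, `alpha_adjusted`, `n_tests`, `n` and
#'   the underlying `lm` fit.
#' @export
multi_fit <- function(data, formula, alpha = 0.05) {
  data <- data[complete.cases(data[, all.vars(formula)]), , drop = FALSE]
  fit <- lm(formula, data = data)
  sm <- summary(fit)
  X <- stats::model.matrix(fit)
  kap <- kappa(scale(X[, -1, drop = FALSE]), exact = TRUE)
  if (!is.finite(kap) || kap > 100) {
    warn(sprintf("covariates are nearly collinear (condition number %.3g)", kap))
  }
  ct <- sm$coefficients
  terms_all <- rownames(ct)
  n_tests <- sum(terms_all != "(Intercept)")
  alpha_adj <- alpha / n_tests
  coefs <- tibble::tibble(
    term = terms_all,
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    t = unname(ct[, "t value"]),
    p = unname(ct[, "Pr(>|t|)"])
  )
  coefs$significant <- coefs$term != "(Intercept)" & coefs$p < alpha_adj
  fs <- sm$fstatistic
  structure(list(
    coefficients = coefs, r_squared = sm$r.squared,
    f_statistic = unname(fs[1]), f_dof = unname(fs[2:3]),
    f_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    alpha_adjusted = alpha_adj, n_tests = n_tests,
    n = nrow(data), lm = fit
  ), class = "multi_fit")
}

#' @export
print.multi_fit <- function(x, ...) {
  cat(sprintf("multiple regression (n = %d): R^2 = %.3f, F(%g, %g) = %.2f, p = %.3g\n",
              x$n, x$r_squared, x$f_dof[1], x$f_dof[2], x$f_statistic, x$f_p))
  cat(sprintf("per-coefficient alpha (Bonferroni over %d tests): %.3g\n",
              x$n_tests, x$alpha_adjusted))
  print(x$coefficients)
  invisible(x)
}

#' Paired test of nightly durations between two sources
#'
#' Convenience wrapper: pairs nights by cycle and runs a paired t-test on
#' the durations (x vs y).
#'
#' @param nights_x,nights_y [night_table()]s for the same subject(s).
#' @return the `htest` object from [t.test()].
#' @export
compare_durations <- function(nights_x, nights_y) {
  pairs <- pair_nights(nights_x, nights_y)
  t.test(pairs$duration_x, pairs$duration_y, paired = TRUE)
}
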