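#' Tidy a cosinor fit
#' @param x a `cosinor_fit`.
#' @param ... unused.
#' @return a tibble with one row per parameter (mesor, amplitude,
#'   acrophase).
#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h)
  )
}

#' One-row summary of a cosinor fit
#' @param x a `cosinor_fit`.
#' @param ... unused.
#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(mesor = x$mesor, amplitude = x$amplitude,
                 acrophase_h = x$acrophase_h, period_h = x$period_h,
                 r_squared = x$r_squared, residual_sd = x$residual_sd,
                 n = x$n)
}

#' Tidy a robust simple regression
#' @param x a `robust_fit`.
#' @param ... unused.
#' @method tidy robust_fit
#' @export
tidy.robust_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$beta),
    statistic = c(NA_real_, x$t),
    p.value = c(NA_real_, x$p)
  )
}

#' One-row summary of a robust simple regression
#' @param x a `robust_fit`.
#' @param ... unused.
#' @method glance robust_fit
#' @export
glance.robust_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$t, df = x$dof,
                 p.value = x$p, nobs = x$n)
}

#' Tidy a Bonferroni-corrected multiple regression
#' @param x a `multi_fit`.
#' @param ... unused.
#' @method tidy multi_fit
#' @export
tidy.multi_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a Bonferroni-corrected multiple regression
#' @param x a `multi_fit`.
#' @param ... unused.
#' @method glance multi_fit
#' @export
glance.multi_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$f_statistic,
                 df = x$f_dof[1], df.residual = x$f_dof[2],
                 p.value = x$f_p, alpha_adjusted = x$alpha_adjusted,
                 nobs = x$n)
}
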