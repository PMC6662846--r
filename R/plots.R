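#' Plot a cosinor fit over its data
#' @param object a `cosinor_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cosinor_fit
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  dat <- object$data
  dat$fitted <- cosinor_predict(object, dat$time)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::labs(x = "local time", y = "activity",
                  title = sprintf("24-h cosinor: mesor %.3g, amplitude %.3g, acrophase %.1f h",
                                  object$mesor, object$amplitude,
                                  object$acrophase_h)) +
    ggplot2::theme_minimal()
}

#' Plot a peri-sleep touch-probability profile
#'
#' Population mean with a +-SD ribbon per 3-min bin; bins significantly
#' above zero (Bonferroni-corrected one-sample t-test) are marked.
#'
#' @param object a `peri_sleep_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot peri_sleep_profile
#' @export
autoplot.peri_sleep_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  anchor <- attr(object, "anchor") %||% "onset"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_offset_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean_p - .data$sd_p),
                                      ymax = .data$mean_p + .data$sd_p),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_p)) +
    ggplot2::geom_point(data = df[df$significant, ],
                        ggplot2::aes(y = .data$mean_p), colour = "#b2182b",
                        size = 0.8) +
    ggplot2::labs(x = sprintf("minutes from %s", anchor),
                  y = "P(touch in 3-min bin)") +
    ggplot2::theme_minimal()
}

#' Plot the touch-probability-by-D histogram
#' @param hist tibble from [touch_by_d_histogram()].
#' @return a ggplot.
#' @export
plot_touch_by_d <- function(hist) {
  hist$label <- ifelse(is.finite(hist$bin_hi),
                       sprintf("%.2f", hist$bin_lo),
                       sprintf(">%.0f", hist$bin_lo))
  hist$label <- factor(hist$label, levels = hist$label)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$label, y = .data$p_touch)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Cole-Kripke D (bin lower edge)",
                  y = "P(touch in 1-min bin)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the distribution of sleep fracture fractions
#' @param sff tibble from [sleep_fracture_fraction()].
#' @return a ggplot.
#' @export
plot_sff <- function(sff) {
  ggplot2::ggplot(sff, ggplot2::aes(x = .data$sff)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "#2166ac", colour = "white") +
    ggplot2::labs(x = "sleep fracture fraction (1 = uninterrupted)",
                  y = "nights") +
    ggplot2::theme_minimal()
}

#' Plot the D series with the sleep threshold
#' @param object a `d_series`.
#' @param threshold sleep threshold drawn as a reference line, default 1.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot d_series
#' @export
autoplot.d_series <- function(object, threshold = 1, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$minute, y = .data$d)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, colour = "#b2182b",
                        linetype = "dashed") +
    ggplot2::labs(x = "local time", y = "Cole-Kripke D") +
    ggplot2::theme_minimal()
}
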