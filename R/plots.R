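# ggplot2 autoplot() methods for the tabular result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_abline
#'   scale_x_log10 scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a box-count curve in log-log scale
#'
#' @param object a `box_count_curve`.
#' @param fit optional `fractal_fit` whose regression line is overlaid.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.box_count_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(as.data.frame(object), aes(x = .data$s, y = .data$n)) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "box size s", y = "N(s)") +
    theme_minimal()
  if (!is.null(fit)) {
    p <- p + geom_abline(slope = -fit$d_f, intercept = log10(fit$C),
                         linetype = "dashed") +
      labs(subtitle = sprintf("d_f = %.3f  (R² = %.4f)", fit$d_f, fit$r_squared))
  }
  p
}

#' Plot a multifractal spectrum
#'
#' @param object an `mf_spectrum`.
#' @param ... unused.
#' @return A ggplot of `D_q` versus `q`.
#' @export
autoplot.mf_spectrum <- function(object, ...) {
  ggplot(as.data.frame(object), aes(x = .data$q, y = .data$d_q)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "q", y = expression(D[q])) +
    theme_minimal()
}

#' Plot a simulated lesion-count series
#'
#' @param object a `kmc_series`.
#' @param fit optional `growth_fit` to overlay.
#' @param ... unused.
#' @return A ggplot of `N_m(t)`.
#' @export
autoplot.kmc_series <- function(object, fit = NULL, ...) {
  p <- ggplot(as.data.frame(object), aes(x = .data$t, y = .data$n_m)) +
    geom_point(shape = 3, alpha = 0.6) +
    labs(x = expression(t ~ "(units of" ~ L^3 ~ "steps)"),
         y = expression(N[m](t))) +
    theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(min(object$t[object$t > 0]), max(object$t), length.out = 200)
    pred <- data.frame(t = tt, n_m = fit$A * tt^fit$alpha * exp(-fit$beta * tt))
    p <- p + geom_line(data = pred, colour = "red", linetype = "dashed") +
      labs(subtitle = sprintf("A = %.3g, alpha = %.3f, beta = %.2g, r = %.5f",
                              fit$A, fit$alpha, fit$beta, fit$correlation))
  }
  p
}

#' @importFrom ggplot2 .data
NULL
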