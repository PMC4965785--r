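#' Plot a fitted survivorship model over the observed age frequencies
#'
#' Observed standardized frequencies as points, the posterior-mean expected
#' frequency curve as a line, and the equal-tailed 95% credible band as a
#' ribbon.
#'
#' @param object A `siler_fit`.
#' @param max_age Oldest age drawn (default: largest observed age).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot siler_fit
#' @export
#' @importFrom ggplot2 autoplot
autoplot.siler_fit <- function(object, max_age = NULL, ...) {
  max_age <- max_age %||% max(object$data$age)
  pred <- predict_age_frequencies(object, max_age = max_age)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$age, y = .data$frequency)) +
    ggplot2::labs(x = "Age (years)", y = "Standardized frequency",
                  title = paste0("Model '", object$model, "'"),
                  subtitle = sprintf("DIC = %.2f", object$dic)) +
    ggplot2::theme_minimal()
}

#' Scatterplot of colony survival against a covariate with the OLS line
#'
#' @param data One row per colony; see [ols_fit()].
#' @param x,y Covariate and survival columns (unquoted).
#' @param conf_low,conf_high Optional columns with credible-interval bounds
#'   drawn as vertical error bars.
#' @return A ggplot object.
#' @export
plot_survival_covariate <- function(data, x, y,
                                    conf_low = NULL, conf_high = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = {{ x }}, y = {{ y }})) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(y = "Annual survival probability") +
    ggplot2::theme_minimal()
  lo <- rlang::enquo(conf_low)
  hi <- rlang::enquo(conf_high)
  if (!rlang::quo_is_null(lo) && !rlang::quo_is_null(hi)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = !!lo, ymax = !!hi), width = 0)
  }
  p
}

#' @export
ggplot2::autoplot
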