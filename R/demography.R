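# Demographic summaries derived from fitted survivorship models: annual and
# age-specific survival, life expectancy, and predicted age structures.

#' Age-specific annual survival S_x
#'
#' Probability of surviving one more year at age `x`:
#' \eqn{S_x = l(x + 1) / l(x)}. Constant under the constant-risk model.
#'
#' @inheritParams siler_survivorship
#' @return Numeric vector of probabilities in `(0, 1]`.
#' @export
age_specific_survival <- function(x, params, model = "siler") {
  siler_survivorship(x + 1, params, model) /
    siler_survivorship(x, params, model)
}

#' Life expectancy from annual survival
#'
#' Under a constant annual survival probability `S` (constant hazard
#' `-log(S)`), mean life expectancy is \eqn{-1 / \ln(S)} years.
#'
#' @param S Annual survival probability (or probabilities), strictly between
#'   0 and 1.
#' @return Life expectancy in years.
#' @export
#' @examples
#' life_expectancy(0.65)
life_expectancy <- function(S) {
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0) || any(S >= 1)) {
    stop("S must lie strictly between 0 and 1", call. = FALSE)
  }
  -1 / log(S)
}

#' Posterior annual survival from a fitted model
#'
#' For a constant-risk fit, each posterior draw maps to an annual survival
#' \eqn{S = e^{-a_2}}; for other models an age must be given and the per-draw
#' age-specific survival \eqn{S_x = l(x+1)/l(x)} is used instead.
#'
#' @param fit A `siler_fit`.
#' @param age Age at which to evaluate survival for non-constant models;
#'   ignored (may be `NULL`) for constant-risk fits.
#' @return One-row tibble with `estimate` (posterior mean), `conf.low` and
#'   `conf.high` (equal-tailed 95% credible interval). The per-draw survival
#'   values are attached as attribute `draws`.
#' @export
posterior_annual_survival <- function(fit, age = NULL) {
  stopifnot(inherits(fit, "siler_fit"))
  if (fit$model == "constant" && is.null(age)) {
    s_draws <- exp(-fit$draws[, "a2"])
  } else if (is.null(age)) {
    stop("fit is not a constant-risk model; supply the age at which to ",
         "evaluate age-specific survival", call. = FALSE)
  } else {
    stopifnot(is.numeric(age), length(age) == 1L, age >= 0)
    s_draws <- apply(fit$draws, 1L, function(row) {
      age_specific_survival(age, theta_to_params(row, fit$model), fit$model)
    })
  }
  qs <- stats::quantile(s_draws, c(0.025, 0.975))
  out <- tibble::tibble(estimate = mean(s_draws),
                        conf.low = qs[[1]], conf.high = qs[[2]])
  attr(out, "draws") <- s_draws
  out
}

#' Expand a positional/named draw into siler_params (inactive -> 0)
#' @noRd
theta_to_params <- function(theta, model) {
  full <- c(a1 = 0, b1 = 0, a2 = 0, a3 = 0, b3 = 0, a = 1, sigma = 0)
  nm <- intersect(names(theta), names(full))
  full[nm] <- theta[nm]
  do.call(siler_params, as.list(full))
}

#' Predicted age-frequency curve with credible intervals
#'
#' Evaluates the expected frequency \eqn{a \lambda^{-x} l(x)} at integer ages
#' for every posterior draw, scaled to a colony of `n_colony` individuals,
#' and summarizes each age by the posterior mean and equal-tailed 95%
#' interval. Also reports the smallest age at which the mean expected count
#' drops below one individual — a pragmatic "maximum predicted age" at the
#' stated colony size.
#'
#' @param fit A `siler_fit`.
#' @param max_age Largest age (years) to predict; must not be below the
#'   largest observed age in the fitted data.
#' @param n_colony Colony size used to scale frequencies to expected counts;
#'   `NULL` leaves predictions on the scale of the fitted frequencies.
#' @return Tibble with columns `age`, `estimate`, `conf.low`, `conf.high`,
#'   and attribute `max_predicted_age` (NA when the mean count never falls
#'   below 1 within `max_age`; always NA when `n_colony` is `NULL`).
#' @export
predict_age_frequencies <- function(fit, max_age, n_colony = NULL) {
  stopifnot(inherits(fit, "siler_fit"))
  if (max_age < max(fit$data$age)) {
    stop("max_age must reach at least the largest observed age (",
         max(fit$data$age), ")", call. = FALSE)
  }
  ages <- 0:max_age
  scale <- if (is.null(n_colony)) 1 else n_colony
  ll <- fit$ln_lambda
  pred <- apply(fit$draws, 1L, function(row) {
    scale * expected_frequency(ages, theta_to_params(row, fit$model),
                               fit$model, ln_lambda = ll)
  })
  pred <- matrix(pred, nrow = length(ages))
  m <- rowMeans(pred)
  qs <- apply(pred, 1L, stats::quantile, probs = c(0.025, 0.975))
  out <- tibble::tibble(age = ages, estimate = m,
                        conf.low = qs[1L, ], conf.high = qs[2L, ])
  max_pred <- NA_real_
  if (!is.null(n_colony) && any(m < 1)) {
    max_pred <- ages[which(m < 1)[1]]
  }
  attr(out, "max_predicted_age") <- max_pred
  out
}

#' Demographic summary of a constant-risk fit
#'
#' Combines annual survival, life expectancy and the predicted maximum age
#' into the per-colony summary typically tabulated in comparative survival
#' studies. Life expectancy is reported two ways: the plug-in
#' \eqn{-1/\ln(\bar S)} at the posterior-mean survival, and the posterior
#' mean of per-draw life expectancies (the latter is never smaller, by
#' Jensen's inequality, since \eqn{-1/\ln S} is convex in `S`).
#'
#' @param fit A `siler_fit` of the constant-risk model.
#' @param colony Optional colony label carried into the output.
#' @param n_colony Optional colony size for the maximum-predicted-age
#'   computation.
#' @param max_age Oldest age scanned for the expected-count-below-1
#'   threshold (default 100).
#' @return One-row tibble: `colony`, `S` (+ CI), `life_expectancy`
#'   (plug-in), `life_expectancy_mean` (per-draw mean), `max_predicted_age`.
#' @export
demographic_summary <- function(fit, colony = NULL, n_colony = NULL,
                                max_age = 100) {
  s <- posterior_annual_survival(fit)
  s_draws <- attr(s, "draws")
  s_draws <- pmin(pmax(s_draws, 1e-12), 1 - 1e-12)
  max_pred <- NA_real_
  if (!is.null(n_colony)) {
    pred <- predict_age_frequencies(fit, max_age, n_colony = n_colony)
    max_pred <- attr(pred, "max_predicted_age")
  }
  tibble::tibble(
    colony = colony %||% "colony",
    S = s$estimate,
    S_conf.low = s$conf.low,
    S_conf.high = s$conf.high,
    life_expectancy = life_expectancy(min(max(s$estimate, 1e-12), 1 - 1e-12)),
    life_expectancy_mean = mean(life_expectancy(s_draws)),
    max_predicted_age = max_pred
  )
}
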