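# Closed-form survivorship mathematics for the Siler family.
#
# Component survivorships (x in years):
#   maturing : l1(x) = exp(-(a1/b1) (1 - e^{-b1 x}))
#   constant : l2(x) = exp(-a2 x)
#   senescing: l3(x) = exp(-(a3/b3) (e^{b3 x} - 1))
# Overall survivorship for a model is the product of its included components;
# equivalently exp(-H(x)) with H the integrated hazard. Both (1 - e^{-bx})/b
# and (e^{bx} - 1)/b are computed via expm1 so the b -> 0 constant-hazard
# limit (value x) is reached continuously.

#' Cumulative hazard over included components (vectorized over x)
#' @noRd
cumulative_hazard <- function(x, params, components) {
  H <- numeric(length(x))
  if ("maturing" %in% components && params$a1 > 0) {
    H <- H + if (params$b1 > 0) {
      params$a1 * (-expm1(-params$b1 * x)) / params$b1
    } else {
      params$a1 * x
    }
  }
  if ("constant" %in% components) {
    H <- H + params$a2 * x
  }
  if ("senescing" %in% components && params$a3 > 0) {
    H <- H + if (params$b3 > 0) {
      params$a3 * expm1(params$b3 * x) / params$b3
    } else {
      params$a3 * x
    }
  }
  H
}

check_ages <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("ages must be finite, non-negative numbers", call. = FALSE)
  }
  x
}

#' Survivorship l(x)
#'
#' Probability of surviving from birth to age `x` under the chosen model:
#' the product of the included component survivorships. `l(0) = 1` and
#' `l` is non-increasing in age for all valid parameter values.
#'
#' @param x Age(s) in years, `>= 0`. Vectorized.
#' @param params A [siler_params()] object (or named vector/list).
#' @param model Model name, one of [siler_models()].
#' @return Numeric vector of survival probabilities in `(0, 1]`.
#' @export
#' @examples
#' siler_survivorship(0:5, siler_params(a2 = -log(0.65)), "constant")
siler_survivorship <- function(x, params, model = "siler") {
  params <- as_siler_params(params)
  exp(-cumulative_hazard(check_ages(x), params, model_components(model)))
}

#' Hazard rate mu(x)
#'
#' Instantaneous mortality rate at age `x`: the sum of the included component
#' hazards \eqn{a_1 e^{-b_1 x}}, \eqn{a_2} and \eqn{a_3 e^{b_3 x}}. Equals
#' `-d log l(x) / dx`.
#'
#' @inheritParams siler_survivorship
#' @return Numeric vector of rates per year, `>= 0`.
#' @export
siler_hazard <- function(x, params, model = "siler") {
  params <- as_siler_params(params)
  check_ages(x)
  components <- model_components(model)
  h <- numeric(length(x))
  if ("maturing" %in% components) {
    h <- h + params$a1 * exp(-params$b1 * x)
  }
  if ("constant" %in% components) {
    h <- h + params$a2
  }
  if ("senescing" %in% components) {
    h <- h + params$a3 * exp(params$b3 * x)
  }
  h
}

#' Expected age frequency under a stable age distribution
#'
#' The expected observed frequency at age `x` for a population growing at
#' rate \eqn{\lambda} per year is \eqn{a \lambda^{-x} l(x)}: the survivorship
#' curve tilted by the stable-age-distribution factor and scaled by the
#' amplitude `a`. With `ln_lambda = 0` (stationary population) and `a = 1`
#' this reduces to the survivorship itself.
#'
#' @inheritParams siler_survivorship
#' @param ln_lambda Natural log of the annual population growth rate
#'   \eqn{\lambda}; 0 means a stationary population, negative values a
#'   declining one.
#' @return Numeric vector of non-negative expected frequencies.
#' @export
#' @examples
#' p <- siler_params(a2 = 0.3, a = 100)
#' expected_frequency(0:3, p, "constant", ln_lambda = -0.1)
expected_frequency <- function(x, params, model = "siler", ln_lambda = 0) {
  params <- as_siler_params(params)
  stopifnot(is.numeric(ln_lambda), length(ln_lambda) == 1L,
            is.finite(ln_lambda))
  params$a * exp(-ln_lambda * x) * siler_survivorship(x, params, model)
}
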