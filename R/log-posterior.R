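# The posterior targeted by the sampler: a normal-error likelihood for the
# standardized frequencies about the expected stable-age frequencies, times
# truncated-normal priors on the active hazard parameters and uniform priors
# on the amplitude and residual SD.

#' Build a fast log-likelihood closure over (positional) theta
#'
#' theta is an unnamed numeric vector ordered as active_params(model):
#' hazard parameters, then a, then sigma.
#' @noRd
make_loglik <- function(data, model, ln_lambda) {
  x <- as.numeric(data$age)
  y <- as.numeric(data$frequency)
  comps <- model_components(model)
  pn <- active_params(model)
  i_a <- match("a", pn)
  i_sigma <- match("sigma", pn)
  i_a1 <- match("a1", pn)
  i_b1 <- match("b1", pn)
  i_a2 <- match("a2", pn)
  i_a3 <- match("a3", pn)
  i_b3 <- match("b3", pn)
  has_mat <- "maturing" %in% comps
  has_const <- "constant" %in% comps
  has_sen <- "senescing" %in% comps
  tilt <- exp(-ln_lambda * x)
  n <- length(x)
  const <- -n / 2 * log(2 * pi)

  function(theta) {
    theta <- unname(theta)
    H <- 0
    if (has_mat) {
      a1 <- theta[i_a1]
      b1 <- theta[i_b1]
      H <- H + if (b1 > 0) a1 * (-expm1(-b1 * x)) / b1 else a1 * x
    }
    if (has_const) {
      H <- H + theta[i_a2] * x
    }
    if (has_sen) {
      a3 <- theta[i_a3]
      b3 <- theta[i_b3]
      H <- H + if (b3 > 0) a3 * expm1(b3 * x) / b3 else a3 * x
    }
    mu <- theta[i_a] * tilt * exp(-H)
    sigma <- theta[i_sigma]
    r <- y - mu
    const - n * log(sigma) - sum(r * r) / (2 * sigma * sigma)
  }
}

#' Build the log-prior closure over positional theta
#'
#' Active hazard parameters: half-normal (dnorm kernel with full constant,
#' support [0, Inf)); a ~ U(0, a_upper); sigma ~ U(0, sigma_upper).
#' Returns -Inf outside support.
#' @noRd
make_logprior <- function(model, priors) {
  pn <- active_params(model)
  i_haz <- which(!pn %in% c("a", "sigma"))
  i_a <- match("a", pn)
  i_sigma <- match("sigma", pn)
  sd0 <- priors$normal_sd
  a_up <- priors$a_upper
  s_up <- priors$sigma_upper

  function(theta) {
    theta <- unname(theta)
    a <- theta[i_a]
    sigma <- theta[i_sigma]
    if (a < 0 || a > a_up || sigma <= 0 || sigma > s_up) {
      return(-Inf)
    }
    if (length(i_haz)) {
      h <- theta[i_haz]
      if (any(h < 0)) {
        return(-Inf)
      }
      sum(stats::dnorm(h, 0, sd0, log = TRUE)) - log(a_up) - log(s_up)
    } else {
      -log(a_up) - log(s_up)
    }
  }
}

#' Log-posterior density of a parameter state
#'
#' The (unnormalized) log posterior for one colony's standardized age
#' frequencies: the sum over ages of normal log-densities of the observed
#' frequency about the expected frequency \eqn{a \lambda^{-x} l(x)}, plus the
#' log-priors of the parameters active in `model`. States outside the prior
#' support (negative hazards, amplitude or sigma outside their uniform
#' bounds) return `-Inf`.
#'
#' @param params [siler_params()] object or named vector/list; must include a
#'   positive `sigma`. Parameters inactive in `model` are ignored.
#' @param data Standardized age-frequency tibble with columns `age` and
#'   `frequency` (see [standardize_ages()]).
#' @param model Model name, one of [siler_models()].
#' @param priors A [prior_spec()]; `NULL` bounds are resolved from `data`.
#' @param ln_lambda Log population growth rate (see [expected_frequency()]).
#' @return A single log-density value (possibly `-Inf`).
#' @export
siler_log_posterior <- function(params, data, model = "siler",
                                priors = prior_spec(), ln_lambda = 0) {
  params <- as_siler_params(params)
  priors <- resolve_priors(priors, data)
  if (nrow(data) == 0) {
    stop("data must be non-empty", call. = FALSE)
  }
  pn <- active_params(model)
  theta <- unlist(params[pn], use.names = FALSE)
  lp <- make_logprior(model, priors)(theta)
  if (!is.finite(lp)) {
    return(-Inf)
  }
  lp + make_loglik(data, model, ln_lambda)(theta)
}
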