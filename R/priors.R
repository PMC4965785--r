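#' Prior specification for Bayesian model fitting
#'
#' Hazard parameters (`a1`, `b1`, `a2`, `a3`, `b3`) receive vague zero-mean
#' normal priors of standard deviation `normal_sd`, truncated at zero because
#' negative hazards do not yield valid survivorship (effectively half-normal
#' priors). The amplitude `a` and residual standard deviation `sigma` receive
#' uniform priors on `(0, a_upper)` and `(0, sigma_upper)`.
#'
#' @param a_upper Upper bound of the uniform prior on the amplitude `a`.
#'   Default `NULL`: resolved at fit time to 10 times the maximum observed
#'   frequency.
#' @param sigma_upper Upper bound of the uniform prior on `sigma`. Default
#'   `NULL`: resolved at fit time to 10 times the standard deviation of the
#'   observed frequencies.
#' @param normal_sd Standard deviation of the (truncated) normal priors on
#'   the hazard parameters. Default 100, i.e. effectively flat on the scale
#'   of plausible hazards.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(a_upper = NULL, sigma_upper = NULL, normal_sd = 100) {
  for (nm in c("a_upper", "sigma_upper", "normal_sd")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0)) {
      stop(nm, " must be a single positive number", call. = FALSE)
    }
  }
  structure(list(a_upper = a_upper, sigma_upper = sigma_upper,
                 normal_sd = normal_sd),
            class = "prior_spec")
}

#' Fill data-driven prior bounds
#' @noRd
resolve_priors <- function(priors, data) {
  stopifnot(inherits(priors, "prior_spec"))
  y <- data$frequency
  if (is.null(priors$a_upper)) {
    priors$a_upper <- 10 * max(y)
  }
  if (is.null(priors$sigma_upper)) {
    sy <- stats::sd(y)
    priors$sigma_upper <- 10 * max(sy, .Machine$double.eps)
  }
  priors
}

#' MCMC sampler configuration
#'
#' @param n_chains Number of independent chains (at least 2; default 3).
#' @param n_iterations Iterations per chain (default 10000).
#' @param burnin_fraction Fraction of each chain discarded as burn-in
#'   (default 0.1).
#' @param thin Keep every `thin`-th post-burn-in draw (default 1; 10 is a
#'   useful setting for thinning comparisons).
#' @param seed Integer seed; chain `i` uses `seed + i`, and fits with the
#'   same configuration are bit-identical.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 10000,
                        burnin_fraction = 0.1, thin = 1, seed = 1L) {
  stopifnot(n_chains >= 2, n_iterations >= 10,
            burnin_fraction >= 0, burnin_fraction < 1,
            thin >= 1, is.numeric(seed), length(seed) == 1L)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burnin_fraction = burnin_fraction,
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}
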