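#' Fit a survivorship model to standardized age frequencies
#'
#' Samples the posterior of the chosen model's active parameters (hazard
#' parameters, amplitude `a`, residual SD `sigma`) by adaptive random-walk
#' Metropolis, starting each chain from a jittered grid-search optimum.
#' Convergence is summarized by split-chain R-hat; fits with any R-hat above
#' 1.1 are flagged (with a warning) but still returned.
#'
#' @param data Standardized age-frequency tibble with columns `age` and
#'   `frequency` (see [standardize_ages()]); at least 3 distinct ages.
#' @param model Model name, one of [siler_models()].
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param ln_lambda Log annual population growth rate assumed when mapping
#'   survivorship to expected age frequencies (0 = stationary).
#' @param grid Optional starting grid passed to [initial_conditions()].
#' @return An object of class `siler_fit`; see [tidy.siler_fit()] and
#'   [glance.siler_fit()] for summaries.
#' @export
#' @examples
#' sim <- simulate_colony(colony_scenario(
#'   params = siler_params(a2 = 0.15), model = "constant",
#'   n_captures = 500, seed = 42))
#' fit <- fit_siler(sim$age_frequencies, "constant",
#'                  config = mcmc_config(n_iterations = 2000, seed = 1))
#' posterior_annual_survival(fit)
fit_siler <- function(data, model = "constant", priors = prior_spec(),
                      config = mcmc_config(), ln_lambda = 0, grid = NULL) {
  model <- match_model(model)
  stopifnot(inherits(config, "mcmc_config"))
  data <- tibble::as_tibble(data)
  if (!all(c("age", "frequency") %in% names(data))) {
    stop("data needs columns 'age' and 'frequency'", call. = FALSE)
  }
  n_ages <- length(unique(data$age))
  if (n_ages < 3) {
    stop("too few distinct ages (", n_ages, "); need at least 3", call. = FALSE)
  }
  pn <- active_params(model)
  if (n_ages <= length(pn)) {
    warning("fewer distinct ages (", n_ages, ") than parameters plus one (",
            length(pn) + 1, "); the posterior may be weakly identified",
            call. = FALSE)
  }
  priors <- resolve_priors(priors, data)

  loglik <- make_loglik(data, model, ln_lambda)
  logprior <- make_logprior(model, priors)
  log_post <- function(theta) {
    lp <- logprior(theta)
    if (!is.finite(lp)) {
      return(list(lp = -Inf, ll = NA_real_))
    }
    ll <- loglik(theta)
    list(lp = lp + ll, ll = ll)
  }

  init <- initial_conditions(data, model, grid = grid, ln_lambda = ln_lambda)
  burn <- floor(config$n_iterations * config$burnin_fraction)
  keep <- seq(burn + 1L, config$n_iterations, by = config$thin)

  chains <- vector("list", config$n_chains)
  logliks <- vector("list", config$n_chains)
  accepts <- numeric(config$n_chains)
  for (i in seq_len(config$n_chains)) {
    set.seed((config$seed %% 1000003L) * 1009L + i) # jitter stream, < 2^31
    start <- jitter_init(init, priors)
    res <- run_chain(log_post, start, config$n_iterations,
                     seed = config$seed + i)
    colnames(res$draws) <- pn
    chains[[i]] <- res$draws
    logliks[[i]] <- res$loglik
    accepts[i] <- res$accept
  }

  kept <- lapply(chains, function(d) d[keep, , drop = FALSE])
  rhat <- split_rhat(kept)
  draws <- do.call(rbind, kept)
  chain_id <- rep(seq_len(config$n_chains), each = length(keep))
  loglik_kept <- unlist(lapply(logliks, `[`, keep), use.names = FALSE)

  mean_dev <- mean(-2 * loglik_kept)
  theta_bar <- colMeans(draws)
  dev_at_mean <- -2 * loglik(theta_bar)
  dic <- mean_dev + (mean_dev - dev_at_mean)

  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  summary <- tibble::tibble(
    term = pn,
    estimate = as.numeric(theta_bar),
    std.error = apply(draws, 2L, stats::sd),
    conf.low = qs[1L, ],
    conf.high = qs[2L, ],
    rhat = as.numeric(rhat)
  )

  converged <- all(rhat <= 1.1)
  if (!converged) {
    warning("convergence not reached: max R-hat = ",
            signif(max(rhat), 4), call. = FALSE)
  }

  structure(list(
    model = model,
    components = model_components(model),
    data = data,
    draws = draws,
    chain = chain_id,
    loglik = loglik_kept,
    summary = summary,
    dic = dic,
    mean_deviance = mean_dev,
    deviance_at_mean = dev_at_mean,
    p_d = mean_dev - dev_at_mean,
    rhat = rhat,
    converged = converged,
    accept_rate = accepts,
    init = init,
    priors = priors,
    config = config,
    ln_lambda = ln_lambda
  ), class = "siler_fit")
}

#' Fit all (or several) candidate models to the same data
#'
#' @inheritParams fit_siler
#' @param models Character vector of model names (default: all five).
#' @return Named list of `siler_fit` objects, suitable for [select_model()].
#' @export
fit_siler_models <- function(data, models = siler_models(),
                             priors = prior_spec(), config = mcmc_config(),
                             ln_lambda = 0) {
  models <- vapply(models, match_model, character(1))
  fits <- lapply(models, function(m) {
    fit_siler(data, m, priors = priors, config = config,
              ln_lambda = ln_lambda)
  })
  names(fits) <- models
  fits
}

#' Assemble a siler_fit from externally supplied posterior draws
#'
#' Useful for computing the deviance information criterion from draws that
#' did not come from [fit_siler()] (e.g. another sampler, or a hand-built
#' chain in a test).
#'
#' @param draws Matrix of posterior draws with columns named as
#'   `active_params(model)` (order free; missing columns are an error).
#' @param data Standardized age-frequency tibble the draws refer to.
#' @param model Model name.
#' @param ln_lambda Log growth rate assumed for the fit.
#' @return A minimal `siler_fit` object with DIC components filled in.
#' @export
siler_fit_from_draws <- function(draws, data, model = "constant",
                                 ln_lambda = 0) {
  model <- match_model(model)
  pn <- active_params(model)
  draws <- as.matrix(draws)
  if (is.null(colnames(draws)) || !all(pn %in% colnames(draws))) {
    stop("draws must have columns: ", paste(pn, collapse = ", "),
         call. = FALSE)
  }
  draws <- draws[, pn, drop = FALSE]
  loglik <- make_loglik(data, model, ln_lambda)
  ll <- apply(draws, 1L, loglik)
  mean_dev <- mean(-2 * ll)
  dev_at_mean <- -2 * loglik(colMeans(draws))
  structure(list(
    model = model,
    components = model_components(model),
    data = tibble::as_tibble(data),
    draws = draws,
    chain = rep(1L, nrow(draws)),
    loglik = ll,
    dic = mean_dev + (mean_dev - dev_at_mean),
    mean_deviance = mean_dev,
    deviance_at_mean = dev_at_mean,
    p_d = mean_dev - dev_at_mean,
    rhat = stats::setNames(rep(NA_real_, length(pn)), pn),
    converged = NA,
    ln_lambda = ln_lambda
  ), class = "siler_fit")
}

#' Deviance information criterion of a fit
#'
#' DIC = D-bar + p_D with p_D = D-bar - D(theta-bar): the posterior mean
#' deviance plus the effective number of parameters, using the
#' likelihood-only deviance (-2 log-likelihood, priors excluded) and the
#' posterior-mean plug-in. Lower is better; differences above 2 units are
#' conventionally taken as meaningful support.
#'
#' @param fit A `siler_fit`.
#' @return The DIC (single number), with attributes `mean_deviance`,
#'   `deviance_at_mean` and `p_d`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "siler_fit"))
  loglik <- make_loglik(fit$data, fit$model, fit$ln_lambda)
  ll <- apply(fit$draws, 1L, loglik)
  mean_dev <- mean(-2 * ll)
  dev_at_mean <- -2 * loglik(colMeans(fit$draws))
  dic <- mean_dev + (mean_dev - dev_at_mean)
  attr(dic, "mean_deviance") <- mean_dev
  attr(dic, "deviance_at_mean") <- dev_at_mean
  attr(dic, "p_d") <- mean_dev - dev_at_mean
  dic
}

#' @export
print.siler_fit <- function(x, ...) {
  cat("Bayesian survivorship fit: model '", x$model, "' (",
      paste(x$components, collapse = " + "), ")\n", sep = "")
  cat(sprintf("  %d draws, DIC = %.2f (p_D = %.2f), max R-hat = %s\n",
              nrow(x$draws), x$dic, x$p_d,
              if (all(is.na(x$rhat))) "NA" else signif(max(x$rhat), 4)))
  if (!is.null(x$summary)) {
    print(x$summary)
  }
  invisible(x)
}

#' Tidy posterior summaries of a fit
#'
#' @param x A `siler_fit`.
#' @param ... Unused.
#' @return Tibble with one row per active parameter: posterior mean
#'   (`estimate`), posterior SD (`std.error`), equal-tailed 95% credible
#'   interval (`conf.low`, `conf.high`) and `rhat`.
#' @method tidy siler_fit
#' @export
#' @importFrom generics tidy
tidy.siler_fit <- function(x, ...) {
  if (!is.null(x$summary)) {
    return(x$summary)
  }
  qs <- apply(x$draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  tibble::tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2L, stats::sd),
    conf.low = qs[1L, ],
    conf.high = qs[2L, ],
    rhat = as.numeric(x$rhat)
  )
}

#' One-row model-level summary of a fit
#'
#' @param x A `siler_fit`.
#' @param ... Unused.
#' @return Tibble with model name, number of hazard parameters, DIC and its
#'   components, maximum R-hat, convergence flag and number of draws.
#' @method glance siler_fit
#' @export
#' @importFrom generics glance
glance.siler_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_hazard_params = n_hazard_params(x$model),
    dic = x$dic,
    mean_deviance = x$mean_deviance,
    p_d = x$p_d,
    max_rhat = if (all(is.na(x$rhat))) NA_real_ else max(x$rhat),
    converged = x$converged,
    n_draws = nrow(x$draws)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
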