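# Synthetic colony generator: age samples drawn from the stable age
# distribution implied by Siler survivorship and a population growth rate,
# with optional capture bias on the 0-year class (young-of-year caught in
# numbers but not tooth-aged) and a configurable sex ratio. Gives the whole
# pipeline realistic inputs without any field data.

#' Describe a synthetic colony scenario
#'
#' @param params True [siler_params()] generating mortality.
#' @param model Generating model, one of [siler_models()].
#' @param ln_lambda Log annual population growth rate (0 = stationary).
#' @param n_captures Total number of captured individuals.
#' @param unaged_juvenile_proportion Proportion of captures that are unaged
#'   0-year juveniles (capture bias), in `[0, 1)`. The count is deterministic
#'   (`floor(proportion * n_captures)`), the remainder being tooth-aged.
#' @param proportion_male Probability a capture is male.
#' @param noise_sd Standard deviation of optional Gaussian perturbation added
#'   to the standardized frequencies (truncated at 0), emulating the normal
#'   observation-error model directly. Default 0: sampling noise alone.
#' @param seed Integer seed making the simulation reproducible.
#' @param colony Colony label.
#' @return An object of class `colony_scenario`.
#' @export
colony_scenario <- function(params, model = "constant", ln_lambda = 0,
                            n_captures = 100,
                            unaged_juvenile_proportion = 0,
                            proportion_male = 0.5, noise_sd = 0,
                            seed = 1L, colony = "synthetic") {
  params <- as_siler_params(params)
  model <- match_model(model)
  stopifnot(n_captures > 0,
            unaged_juvenile_proportion >= 0, unaged_juvenile_proportion < 1,
            proportion_male >= 0, proportion_male <= 1,
            noise_sd >= 0)
  structure(list(params = params, model = model, ln_lambda = ln_lambda,
                 n_captures = as.integer(n_captures),
                 unaged_juvenile_proportion = unaged_juvenile_proportion,
                 proportion_male = proportion_male, noise_sd = noise_sd,
                 seed = as.integer(seed), colony = colony),
            class = "colony_scenario")
}

#' Stable age distribution over integer ages
#'
#' Probability that a randomly encountered individual is of integer age `x`
#' in a population with survivorship `l(x)` growing at rate \eqn{\lambda}:
#' \eqn{p(x) \propto \lambda^{-x} l(x)}, normalized to sum to 1. With
#' `ln_lambda = 0` this is the stationary age structure; for a constant
#' hazard it is geometric with ratio \eqn{e^{-a_2}}.
#'
#' @inheritParams siler_survivorship
#' @param ln_lambda Log annual population growth rate.
#' @param max_age Oldest age included. Default `NULL`: extended automatically
#'   until the per-age weight falls below `tail_mass` relative to the total.
#' @param tail_mass Relative tail-weight threshold for the automatic
#'   truncation (default 1e-6).
#' @return Tibble with columns `age` and `prob` (summing to 1).
#' @export
#' @examples
#' stable_age_distribution(siler_params(a2 = 0.3), "constant")
stable_age_distribution <- function(params, model = "siler", ln_lambda = 0,
                                    max_age = NULL, tail_mass = 1e-6) {
  params <- as_siler_params(params)
  weight <- function(x) {
    exp(-ln_lambda * x) * siler_survivorship(x, params, model)
  }
  cap <- 10000L
  if (is.null(max_age)) {
    ages <- 0:200
    w <- weight(ages)
    while (all(is.finite(w)) && w[length(w)] > tail_mass * sum(w)) {
      if (length(ages) - 1L >= cap) {
        stop("stable age distribution is not normalizable: the growth tilt ",
             "lambda^(-x) outpaces mortality; use a more negative hazard or ",
             "a larger ln_lambda", call. = FALSE)
      }
      ages <- 0:min(2L * (length(ages) - 1L), cap)
      w <- weight(ages)
    }
    if (any(!is.finite(w))) {
      stop("stable age distribution is not normalizable: the growth tilt ",
           "lambda^(-x) outpaces mortality; use a more negative hazard or ",
           "a larger ln_lambda", call. = FALSE)
    }
    keep <- seq_len(max(which(w > tail_mass * sum(w))))
    ages <- ages[keep]
    w <- w[keep]
  } else {
    stopifnot(max_age >= 1)
    ages <- 0:max_age
    w <- weight(ages)
    if (w[length(w)] > 1e-3 * sum(w)) {
      warning("appreciable probability mass at max_age; distribution is ",
              "truncated", call. = FALSE)
    }
  }
  tibble::tibble(age = ages, prob = w / sum(w))
}

#' Simulate one colony's capture data
#'
#' Draws `n_captures` individuals: a deterministic
#' `floor(unaged_juvenile_proportion * n_captures)` unaged 0-year juveniles,
#' the remainder tooth-aged with integer ages sampled from the stable age
#' distribution (conditioned on age >= 1 when the capture bias is positive),
#' and sexes drawn Bernoulli(`proportion_male`). Also returns the
#' standardized age frequencies (via [standardize_ages()]), optionally
#' perturbed by Gaussian noise truncated at zero.
#'
#' @param scenario A [colony_scenario()].
#' @return List of class `colony_sim` with elements `records` (per-individual
#'   tibble: `colony`, `age_years`, `life_stage`, `sex`, `certainty`,
#'   `phase`), `age_frequencies` (standardized tibble) and `scenario`.
#' @export
#' @examples
#' sim <- simulate_colony(colony_scenario(
#'   params = siler_params(a2 = -log(0.65)), model = "constant",
#'   n_captures = 200, seed = 7))
#' head(sim$records)
simulate_colony <- function(scenario) {
  stopifnot(inherits(scenario, "colony_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_captures
  p_bias <- scenario$unaged_juvenile_proportion
  n_unaged <- as.integer(floor(p_bias * n))
  n_aged <- n - n_unaged

  sad <- stable_age_distribution(scenario$params, scenario$model,
                                 scenario$ln_lambda)
  if (p_bias > 0) {
    sad <- sad[sad$age >= 1, , drop = FALSE]
    sad$prob <- sad$prob / sum(sad$prob)
  }
  ages <- sample(sad$age, n_aged, replace = TRUE, prob = sad$prob)
  sexes <- ifelse(stats::runif(n) < scenario$proportion_male, "M", "F")

  records <- tibble::tibble(
    colony = scenario$colony,
    age_years = c(rep(NA_integer_, n_unaged), as.integer(ages)),
    life_stage = c(rep("unaged_juvenile", n_unaged), rep("aged", n_aged)),
    sex = sexes,
    certainty = "A",
    phase = NA_character_
  )

  af <- standardize_ages(records)
  if (scenario$noise_sd > 0) {
    af$frequency <- pmax(
      af$frequency + stats::rnorm(nrow(af), 0, scenario$noise_sd), 0)
  }
  structure(list(records = records, age_frequencies = af,
                 scenario = scenario),
            class = "colony_sim")
}
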