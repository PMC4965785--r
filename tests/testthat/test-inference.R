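test_that("log-posterior matches a term-by-term scalar oracle", {
  data <- tibble::tibble(age = c(0, 2, 5), frequency = c(0.5, 0.3, 0.1))
  pri <- prior_spec(a_upper = 5, sigma_upper = 2, normal_sd = 100)
  p <- siler_params(a1 = 0.4, b1 = 0.9, a2 = 0.12, a3 = 0.02, b3 = 0.25,
                    a = 0.6, sigma = 0.05)

  mu <- vapply(data$age, function(x) {
    l1 <- exp(-(p$a1 / p$b1) * (1 - exp(-p$b1 * x)))
    l2 <- exp(-p$a2 * x)
    l3 <- exp((p$a3 / p$b3) * (1 - exp(p$b3 * x)))
    p$a * l1 * l2 * l3
  }, numeric(1))
  oracle <- sum(dnorm(data$frequency, mu, p$sigma, log = TRUE)) +
    sum(dnorm(c(p$a1, p$b1, p$a2, p$a3, p$b3), 0, 100, log = TRUE)) +
    dunif(p$a, 0, 5, log = TRUE) + dunif(p$sigma, 0, 2, log = TRUE)

  expect_equal(siler_log_posterior(p, data, "siler", pri), oracle,
               tolerance = 1e-10)
})

test_that("zero residuals attain the normal-likelihood maximum", {
  sigma <- 0.04
  p <- siler_params(a2 = 0.3, a = 0.8, sigma = sigma)
  data <- tibble::tibble(age = 0:6,
                         frequency = expected_frequency(0:6, p, "constant"))
  pri <- prior_spec(a_upper = 10, sigma_upper = 1)
  lp <- siler_log_posterior(p, data, "constant", pri)
  prior_part <- dnorm(0.3, 0, 100, log = TRUE) +
    dunif(0.8, 0, 10, log = TRUE) + dunif(sigma, 0, 1, log = TRUE)
  expect_equal(lp - prior_part, 7 * (-0.5 * log(2 * pi * sigma^2)),
               tolerance = 1e-10)
  # any perturbed frequency vector can only lower the likelihood
  worse <- data
  worse$frequency[3] <- worse$frequency[3] + 0.01
  expect_lt(siler_log_posterior(p, worse, "constant", pri), lp)
})

test_that("states outside the prior support have zero density", {
  data <- tibble::tibble(age = 0:4, frequency = c(0.4, 0.25, 0.18, 0.1, 0.07))
  pri <- prior_spec(a_upper = 1, sigma_upper = 0.5)
  expect_identical(
    siler_log_posterior(siler_params(a2 = 0.2, a = 1.5, sigma = 0.1),
                        data, "constant", pri), -Inf)
  expect_identical(
    siler_log_posterior(siler_params(a2 = 0.2, a = 0.5, sigma = 0),
                        data, "constant", pri), -Inf)
  expect_identical(
    siler_log_posterior(siler_params(a2 = 0.2, a = 0.5, sigma = 0.9),
                        data, "constant", pri), -Inf)
})

test_that("the MCMC target equals the public log-posterior at random states", {
  data <- sim_constant_colony(S = 0.75, n = 400, seed = 9)$age_frequencies
  pri <- prior_spec(a_upper = 3, sigma_upper = 1)
  set.seed(31)
  for (model in c("constant", "siler", "maturation_senescence")) {
    pn <- silerfit:::active_params(model)
    ll <- silerfit:::make_loglik(data, model, ln_lambda = 0)
    lp <- silerfit:::make_logprior(model, pri)
    for (i in 1:10) {
      theta <- stats::runif(length(pn), 0.01, 0.9)
      names(theta) <- pn
      expect_equal(lp(unname(theta)) + ll(unname(theta)),
                   siler_log_posterior(theta, data, model, pri),
                   tolerance = 1e-10)
    }
  }
})

test_that("grid search finds the zero-RSS generating point", {
  data <- exact_constant_data(0.3)
  init <- initial_conditions(data, "constant",
                             grid = list(a2 = c(0.1, 0.3, 0.6),
                                         a = c(0.5, 1, 2)))
  expect_equal(init[["a2"]], 0.3)
  expect_equal(init[["a"]], 1)
  expect_lt(attr(init, "rss"), 1e-20)
})

test_that("a singleton grid is returned as-is and refinement never hurts", {
  data <- sim_constant_colony(S = 0.7, n = 300, seed = 5)$age_frequencies
  single <- initial_conditions(data, "constant",
                               grid = list(a2 = 0.4, a = 0.2))
  expect_equal(single[["a2"]], 0.4)
  expect_equal(single[["a"]], 0.2)

  coarse <- initial_conditions(data, "constant",
                               grid = list(a2 = c(0.2, 0.5), a = c(0.2, 0.4)))
  fine <- initial_conditions(data, "constant",
                             grid = list(a2 = seq(0.1, 0.6, by = 0.05),
                                         a = seq(0.1, 0.5, by = 0.05)))
  expect_gte(attr(coarse, "rss"), attr(fine, "rss"))
})

test_that("fitting is deterministic under a fixed seed", {
  data <- sim_constant_colony(S = 0.8, n = 500, seed = 21)$age_frequencies
  cfg <- mcmc_config(n_iterations = 1500, seed = 77)
  f1 <- fit_siler(data, "constant", config = cfg)
  f2 <- fit_siler(data, "constant", config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$dic, f2$dic)
})

test_that("constant fit recovers the generating survival", {
  data <- sim_constant_colony(S = 0.86, n = 1500, seed = 1)$age_frequencies
  fit <- fit_siler(data, "constant", config = mcmc_config(seed = 4))
  s <- posterior_annual_survival(fit)
  expect_lt(abs(s$estimate - 0.86), 0.03)
  expect_true(all(fit$rhat < 1.1))
  expect_true(fit$converged)
})

test_that("thinned and unthinned runs agree within Monte-Carlo error", {
  data <- sim_constant_colony(S = 0.8, n = 800, seed = 13)$age_frequencies
  f1 <- fit_siler(data, "constant", config = mcmc_config(seed = 3, thin = 1))
  f10 <- fit_siler(data, "constant", config = mcmc_config(seed = 6, thin = 10))
  for (term in c("a2", "a", "sigma")) {
    mcse <- function(f) {
      x <- f$draws[, term]
      stats::sd(x) / sqrt(coda::effectiveSize(coda::mcmc(x)))
    }
    d <- abs(mean(f1$draws[, term]) - mean(f10$draws[, term]))
    expect_lt(d, 2 * (mcse(f1) + mcse(f10)) + 1e-8)
  }
})

test_that("independent sampler (JAGS) reproduces the constant-model posterior", {
  data <- sim_constant_colony(S = 0.86, n = 1500, seed = 106)$age_frequencies
  fit <- fit_siler(data, "constant", config = mcmc_config(seed = 206))

  model_str <- "model {
    for (i in 1:n) { y[i] ~ dnorm(a * exp(-a2 * x[i]), tau) }
    a2 ~ dnorm(0, 1e-4) T(0,)
    a ~ dunif(0, a_up)
    sigma ~ dunif(0, s_up)
    tau <- 1 / (sigma * sigma)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = data$frequency, x = data$age, n = nrow(data),
                a_up = 10 * max(data$frequency),
                s_up = 10 * sd(data$frequency)),
    n.chains = 2,
    inits = list(
      list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1),
      list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 2)),
    quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  sm <- summary(rjags::coda.samples(jm, c("a2", "a", "sigma"), 8000,
                                    progress.bar = "none"))
  mine <- tidy(fit)
  for (term in c("a", "a2", "sigma")) {
    m_est <- mine$estimate[mine$term == term]
    j_est <- sm$statistics[term, "Mean"]
    j_sd <- sm$statistics[term, "SD"]
    expect_lt(abs(m_est - j_est), 0.25 * j_sd + 1e-6)
    expect_lt(abs(mine$std.error[mine$term == term] - j_sd), 0.3 * j_sd)
  }
})

test_that("DIC of a degenerate chain has zero effective parameters", {
  data <- tibble::tibble(age = 0:4, frequency = c(0.4, 0.25, 0.18, 0.1, 0.07))
  draws <- matrix(rep(c(0.3, 0.42, 0.05), each = 50), ncol = 3,
                  dimnames = list(NULL, c("a2", "a", "sigma")))
  fit <- siler_fit_from_draws(draws, data, "constant")
  expect_equal(fit$p_d, 0, tolerance = 1e-10)
  expect_equal(fit$dic, fit$mean_deviance, tolerance = 1e-10)
})

test_that("DIC matches hand arithmetic on a tiny chain", {
  data <- tibble::tibble(age = c(0, 1), frequency = c(0.6, 0.35))
  draws <- cbind(a2 = c(0.4, 0.5, 0.45, 0.55),
                 a = c(0.6, 0.62, 0.58, 0.6),
                 sigma = c(0.05, 0.06, 0.05, 0.07))
  fit <- siler_fit_from_draws(draws, data, "constant")

  dev_of <- function(a2, a, sigma) {
    -2 * sum(dnorm(data$frequency, a * exp(-a2 * data$age), sigma, log = TRUE))
  }
  devs <- mapply(dev_of, draws[, "a2"], draws[, "a"], draws[, "sigma"])
  d_bar <- mean(devs)
  d_at_mean <- dev_of(mean(draws[, "a2"]), mean(draws[, "a"]),
                      mean(draws[, "sigma"]))
  expect_equal(fit$dic, d_bar + (d_bar - d_at_mean), tolerance = 1e-10)
  expect_equal(compute_dic(fit), fit$dic, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("an always-inactive component leaves the DIC unchanged", {
  data <- tibble::tibble(age = 0:5,
                         frequency = c(0.35, 0.25, 0.17, 0.11, 0.07, 0.05))
  set.seed(8)
  base <- cbind(a2 = runif(40, 0.2, 0.5), a = runif(40, 0.3, 0.5),
                sigma = runif(40, 0.02, 0.08))
  f_const <- siler_fit_from_draws(base, data, "constant")
  f_mat <- siler_fit_from_draws(
    cbind(a1 = 0, b1 = 0.5, base), data, "maturation")
  expect_equal(f_mat$dic, f_const$dic, tolerance = 1e-12)
})

test_that("model comparison enforces its preconditions", {
  data <- tibble::tibble(age = 0:2, frequency = c(0.5, 0.3, 0.2))
  other <- tibble::tibble(age = 0:2, frequency = c(0.6, 0.25, 0.15))
  draws <- cbind(a2 = c(0.4, 0.5), a = c(0.6, 0.62), sigma = c(0.05, 0.06))
  f1 <- siler_fit_from_draws(draws, data, "constant")
  f2 <- siler_fit_from_draws(cbind(a1 = 0.1, b1 = 0.5, draws), other,
                             "maturation")
  expect_error(select_model(list(f1, f2)), "same data")
  expect_error(select_model(list(f1)), "at least two")
  expect_error(fit_siler(tibble::tibble(age = c(0, 1), frequency = c(0.6, 0.4)),
                         "constant"), "too few distinct ages")
})
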