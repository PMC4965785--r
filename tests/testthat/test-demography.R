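test_that("age-specific survival follows l(x+1)/l(x)", {
  expect_equal(age_specific_survival(0:10, siler_params(a2 = 0.43078), "constant"),
               rep(exp(-0.43078), 11), tolerance = 1e-12)
  expect_equal(age_specific_survival(3, siler_params(), "constant"), 1)

  p <- siler_params(a1 = 0.5, b1 = 1, a2 = 0.1, a3 = 0.01, b3 = 0.3)
  expect_equal(age_specific_survival(1, p, "siler"),
               quad_survivorship(2, p, "siler") / quad_survivorship(1, p, "siler"),
               tolerance = 1e-8)
})

test_that("life expectancy converts survival as -1/log(S)", {
  expect_equal(round(life_expectancy(0.65), 2), 2.32)
  expect_equal(life_expectancy(exp(-1)), 1, tolerance = 1e-12)
  expect_equal(life_expectancy(0.5), 1 / log(2), tolerance = 1e-12)
  expect_equal(life_expectancy(0.5), 1.4427, tolerance = 1e-4)
  expect_error(life_expectancy(1), "between 0 and 1")
  expect_error(life_expectancy(0), "between 0 and 1")
  expect_error(life_expectancy(-0.2), "between 0 and 1")
  # strictly increasing in S (decreasing in mortality)
  s_grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(life_expectancy(s_grid)) > 0))
})

test_that("posterior survival is the transform of the a2 draws", {
  data <- tibble::tibble(age = 0:4, frequency = c(0.4, 0.25, 0.18, 0.1, 0.07))

  # point mass: zero-width interval at exp(-a2)
  pm <- matrix(rep(c(0.43078, 0.42, 0.05), each = 30), ncol = 3,
               dimnames = list(NULL, c("a2", "a", "sigma")))
  s <- posterior_annual_survival(siler_fit_from_draws(pm, data, "constant"))
  expect_equal(s$estimate, 0.65, tolerance = 1e-5)
  expect_equal(s$conf.high - s$conf.low, 0)

  # spread draws: mean and interval match the transformed empirical quantiles
  set.seed(12)
  a2_draws <- rnorm(4000, 0.15, sqrt(0.001))
  a2_draws <- a2_draws[a2_draws > 0]
  dm <- cbind(a2 = a2_draws, a = 0.4, sigma = 0.05)
  s2 <- posterior_annual_survival(siler_fit_from_draws(dm, data, "constant"))
  expect_equal(s2$estimate, mean(exp(-a2_draws)), tolerance = 1e-12)
  expect_equal(s2$estimate, exp(-0.15), tolerance = 0.01)
  expect_equal(unname(c(s2$conf.low, s2$conf.high)),
               unname(quantile(exp(-a2_draws), c(0.025, 0.975))),
               tolerance = 1e-12)

  # draws containing a2 = 0 map to S = 1 but stay within (0, 1]
  dz <- cbind(a2 = c(0, 0.1, 0.2), a = 0.4, sigma = 0.05)
  s3 <- posterior_annual_survival(siler_fit_from_draws(dz, data, "constant"))
  expect_true(s3$conf.high <= 1 && s3$estimate > 0 && s3$estimate <= 1)

  # non-constant fits require an age
  dm5 <- cbind(a1 = 0.2, b1 = 0.5, a2 = 0.1, a3 = 0.01, b3 = 0.2,
               a = 0.4, sigma = 0.05)[rep(1, 10), ]
  f5 <- siler_fit_from_draws(dm5, data, "siler")
  expect_error(posterior_annual_survival(f5), "age")
  s5 <- posterior_annual_survival(f5, age = 1)
  p5 <- siler_params(a1 = 0.2, b1 = 0.5, a2 = 0.1, a3 = 0.01, b3 = 0.2)
  expect_equal(s5$estimate, age_specific_survival(1, p5, "siler"),
               tolerance = 1e-12)
})

test_that("point-mass predictions reduce to the survivorship curve", {
  data <- tibble::tibble(age = 0:4, frequency = exp(-0.2 * (0:4)))
  pm <- matrix(rep(c(0.2, 1, 0.01), each = 20), ncol = 3,
               dimnames = list(NULL, c("a2", "a", "sigma")))
  fit <- siler_fit_from_draws(pm, data, "constant")
  pred <- predict_age_frequencies(fit, max_age = 10, n_colony = 1)
  expect_equal(pred$estimate, exp(-0.2 * (0:10)), tolerance = 1e-12)
  expect_equal(pred$conf.low, pred$conf.high, tolerance = 1e-12)

  # log-linear in age: perfect fit on the log scale
  lf <- suppressWarnings(lm(log(pred$estimate) ~ pred$age))
  expect_equal(suppressWarnings(summary(lf))$r.squared, 1, tolerance = 1e-10)
})

test_that("maximum predicted age is where the expected count drops below one", {
  data <- tibble::tibble(age = 0:4, frequency = exp(-0.15082 * (0:4)))
  a2 <- -log(0.86)
  pm <- matrix(rep(c(a2, 1, 0.01), each = 20), ncol = 3,
               dimnames = list(NULL, c("a2", "a", "sigma")))
  fit <- siler_fit_from_draws(pm, data, "constant")
  # amplitude 1: scale so expected count at age 0 is 100
  pred <- predict_age_frequencies(fit, max_age = 60, n_colony = 100)
  expect_equal(pred$estimate[1], 100, tolerance = 1e-9)
  expect_equal(attr(pred, "max_predicted_age"), ceiling(log(100) / 0.15082))
  expect_equal(attr(pred, "max_predicted_age"), 31)
})

test_that("credible bands do not narrow when extrapolating beyond the data", {
  data <- sim_constant_colony(S = 0.75, n = 400, seed = 17)$age_frequencies
  fit <- fit_siler(data, "constant",
                   config = mcmc_config(n_iterations = 3000, seed = 2))
  pred <- predict_age_frequencies(fit, max_age = max(data$age) + 15)
  width <- pred$conf.high - pred$conf.low
  rel_width <- width / pmax(pred$estimate, 1e-12)
  beyond <- pred$age >= max(data$age)
  expect_true(all(diff(rel_width[beyond]) > -1e-6))
  expect_error(predict_age_frequencies(fit, max_age = 2), "largest observed age")
})

test_that("plug-in and per-draw life expectancies obey Jensen's inequality", {
  data <- sim_constant_colony(S = 0.8, n = 600, seed = 23)$age_frequencies
  fit <- fit_siler(data, "constant",
                   config = mcmc_config(n_iterations = 3000, seed = 9))
  ds <- demographic_summary(fit, colony = "sim", n_colony = 600)
  expect_gte(ds$life_expectancy_mean, ds$life_expectancy - 1e-10)
  expect_true(ds$S > 0 && ds$S < 1)
  expect_gt(ds$life_expectancy, 0)
  expect_true(is.finite(ds$max_predicted_age))
})
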