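# Grid search for starting values, in the spirit of brute-force non-linear
# least squares: evaluate the residual sum of squares between the observed
# frequencies and the expected frequencies over a coarse grid of parameter
# values and start the chains near the best grid point.

#' Default starting grid for a model
#' @noRd
default_grid <- function(data, model) {
  y_max <- max(data$frequency)
  grid <- list(
    a1 = c(0.05, 0.25, 0.5, 1, 2),
    b1 = c(0.25, 0.5, 1, 2),
    a2 = c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8),
    a3 = c(0.001, 0.005, 0.02, 0.08),
    b3 = c(0.1, 0.3, 0.6, 1),
    a  = y_max * c(0.5, 1, 1.5, 2.5)
  )
  grid[c(model_hazard_params(model), "a")]
}

#' Grid-search initial conditions
#'
#' Returns the grid point minimizing the residual sum of squares (RSS)
#' between observed and expected frequencies, with `sigma` initialized to
#' the residual standard deviation at that point.
#'
#' @param data Standardized age-frequency tibble (`age`, `frequency`).
#' @param model Model name, one of [siler_models()].
#' @param grid Named list of candidate values for each active parameter
#'   (hazard parameters and `a`). Default: a built-in coarse grid scaled to
#'   the data.
#' @param ln_lambda Log population growth rate used in the expected
#'   frequencies.
#' @return Named numeric vector over `active_params(model)` (hazard
#'   parameters, `a`, `sigma`), with attribute `rss`.
#' @export
initial_conditions <- function(data, model = "siler", grid = NULL,
                               ln_lambda = 0) {
  if (is.null(grid)) {
    grid <- default_grid(data, model)
  }
  need <- c(model_hazard_params(model), "a")
  missing <- setdiff(need, names(grid))
  if (length(missing)) {
    stop("grid is missing values for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- grid[need]
  stopifnot(all(vapply(grid, function(g) length(g) > 0 && all(is.finite(g)),
                       logical(1))))
  points <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  ll <- make_loglik(data, model, ln_lambda)
  pn <- active_params(model)
  y <- data$frequency
  n <- length(y)

  rss_of <- function(row) {
    theta <- numeric(length(pn))
    theta[match(colnames(points), pn)] <- row
    theta[match("sigma", pn)] <- 1
    # recover RSS from the unit-sigma gaussian log-likelihood
    if (any(row < 0)) return(Inf)
    -2 * (ll(theta) + n / 2 * log(2 * pi))
  }
  rss <- apply(points, 1L, rss_of)
  if (!any(is.finite(rss))) {
    stop("no valid grid point (all residual sums of squares non-finite)",
         call. = FALSE)
  }
  best <- points[which.min(rss), ]
  theta <- numeric(length(pn))
  names(theta) <- pn
  theta[colnames(points)] <- best
  theta["sigma"] <- max(sqrt(min(rss, na.rm = TRUE) / n), 1e-6)
  attr(theta, "rss") <- min(rss, na.rm = TRUE)
  theta
}

#' Randomized per-chain jitter around the grid optimum
#'
#' Multiplicative lognormal jitter (10% scale) on positive entries; entries
#' at zero get a small half-normal perturbation so every chain starts inside
#' the support at a distinct point.
#' @noRd
jitter_init <- function(init, priors) {
  out <- init
  for (i in seq_along(out)) {
    out[i] <- if (out[i] > 0) {
      out[i] * exp(stats::rnorm(1, 0, 0.1))
    } else {
      abs(stats::rnorm(1, 0, 0.01))
    }
  }
  out["a"] <- min(out["a"], priors$a_upper * 0.99)
  out["sigma"] <- min(max(out["sigma"], 1e-8), priors$sigma_upper * 0.99)
  out
}
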