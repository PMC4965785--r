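# Shared oracles and fixture builders.

# Independent survivorship oracle: adaptive quadrature of the hazard.
quad_survivorship <- function(x, params, model) {
  vapply(x, function(xi) {
    if (xi == 0) {
      return(1)
    }
    exp(-stats::integrate(function(t) siler_hazard(t, params, model),
                          0, xi, rel.tol = 1e-12, abs.tol = 1e-14)$value)
  }, numeric(1))
}

# Random valid parameter sets for property-style tests.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    siler_params(
      a1 = stats::runif(1, 0, 2),
      b1 = stats::runif(1, 0.05, 2),
      a2 = stats::runif(1, 0.01, 0.8),
      a3 = stats::runif(1, 0, 0.1),
      b3 = stats::runif(1, 0.05, 1)
    )
  })
}

# Noise-free constant-hazard age-frequency data.
exact_constant_data <- function(a2, ages = 0:12, a = 1) {
  tibble::tibble(age = ages, frequency = a * exp(-a2 * ages))
}

# Per-individual records with given ages (and optional certainty codes).
records_of <- function(ages, certainty = NULL, colony = "test") {
  out <- tibble::tibble(colony = colony, age_years = ages)
  if (!is.null(certainty)) {
    out$certainty <- certainty
  }
  out
}

# Standard small simulated colony for fitting tests.
sim_constant_colony <- function(S = 0.86, n = 1500, seed = 1) {
  simulate_colony(colony_scenario(
    params = siler_params(a2 = -log(S)), model = "constant",
    n_captures = n, seed = seed))
}
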