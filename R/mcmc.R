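# Adaptive random-walk Metropolis sampler.
#
# Joint normal proposals with a running-covariance (Haario-style) adaptation
# plus Robbins-Monro tuning of a global log-scale toward the classic 0.234
# acceptance rate. Adaptation diminishes as 1/(t+10)^0.6, preserving
# ergodicity. The target is the closure built from make_loglik/make_logprior,
# so the sampled density is exactly siler_log_posterior.

#' Run one chain
#' @param log_post function(theta) -> list(lp, ll)
#' @return list(draws = iterations x d matrix, loglik = vector, accept = rate)
#' @noRd
run_chain <- function(log_post, init, n_iter, seed) {
  set.seed(seed)
  d <- length(init)
  theta <- as.numeric(init)
  cur <- log_post(theta)
  if (!is.finite(cur$lp)) {
    stop("initial state has zero posterior density", call. = FALSE)
  }
  draws <- matrix(NA_real_, n_iter, d)
  ll_store <- numeric(n_iter)
  mean_vec <- theta
  cov_mat <- diag(pmax(theta^2 * 0.01, 1e-8), d)
  chol_S <- chol(cov_mat)
  log_scale <- 0
  base <- 2.38 / sqrt(d)
  n_accept <- 0L

  for (t in seq_len(n_iter)) {
    z <- stats::rnorm(d)
    prop <- theta + exp(log_scale) * base * drop(z %*% chol_S)
    cand <- log_post(prop)
    log_alpha <- cand$lp - cur$lp
    alpha <- if (is.finite(log_alpha)) min(1, exp(log_alpha)) else 0
    if (alpha > 0 && stats::runif(1) < alpha) {
      theta <- prop
      cur <- cand
      n_accept <- n_accept + 1L
    }
    draws[t, ] <- theta
    ll_store[t] <- cur$ll
    gam <- 1 / (t + 10)^0.6
    log_scale <- log_scale + gam * (alpha - 0.234)
    delta <- theta - mean_vec
    mean_vec <- mean_vec + gam * delta
    cov_mat <- cov_mat + gam * (tcrossprod(delta) - cov_mat)
    if (t %% 25L == 0L) {
      ch <- tryCatch(chol(cov_mat + diag(1e-10, d)), error = function(e) NULL)
      if (!is.null(ch)) chol_S <- ch
    }
  }
  list(draws = draws, loglik = ll_store, accept = n_accept / n_iter)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic Gelman-Rubin statistic computed after splitting each chain in
#' half. Parameters with (numerically) zero within-chain variance return 1.
#'
#' @param chains List of draw matrices (iterations x parameters), one per
#'   chain, equal dimensions.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
split_rhat <- function(chains) {
  stopifnot(length(chains) >= 1)
  d <- ncol(chains[[1]])
  half <- floor(nrow(chains[[1]]) / 2)
  pieces <- list()
  for (ch in chains) {
    pieces <- c(pieces, list(ch[seq_len(half), , drop = FALSE],
                             ch[half + seq_len(half), , drop = FALSE]))
  }
  m <- length(pieces)
  n <- half
  out <- numeric(d)
  for (j in seq_len(d)) {
    means <- vapply(pieces, function(p) mean(p[, j]), numeric(1))
    vars <- vapply(pieces, function(p) stats::var(p[, j]), numeric(1))
    w <- mean(vars)
    b <- n * stats::var(means)
    if (!is.finite(w) || w < 1e-12) {
      out[j] <- 1
    } else {
      var_plus <- (n - 1) / n * w + b / n
      out[j] <- sqrt(var_plus / w)
    }
  }
  nm <- colnames(chains[[1]])
  if (!is.null(nm)) names(out) <- nm
  out
}
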