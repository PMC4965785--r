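#' Regress colony survival estimates on a colony-level covariate
#'
#' Simple ordinary least-squares regression (via [stats::lm()]) of per-colony
#' annual survival estimates against one covariate such as population size,
#' hunting-pressure rank, or proportion of males, with the overall F-test on
#' (1, n-2) degrees of freedom.
#'
#' @param data Data frame with one row per colony.
#' @param x,y Column names (unquoted or strings) of the covariate and the
#'   survival estimate.
#' @param weights Optional column of regression weights (e.g. inverse
#'   credible-interval widths); default unweighted, matching the usual
#'   unweighted treatment of colony-level survival regressions.
#' @return One-row tibble: `slope`, `intercept`, `f_statistic`, `p_value`,
#'   `r_squared`, `df_num`, `df_den`, `n`. The underlying `lm` fit is
#'   attached as attribute `fit`.
#' @export
#' @examples
#' colonies <- tibble::tibble(
#'   proportion_male = c(0.91, 0.39, 0.74, 0.46, 0.53),
#'   survival = c(0.74, 0.86, 0.86, 0.77, 0.65))
#' ols_fit(colonies, proportion_male, survival)
ols_fit <- function(data, x, y, weights = NULL) {
  data <- tibble::as_tibble(data)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  wq <- rlang::enquo(weights)
  wv <- if (rlang::quo_is_null(wq)) NULL else dplyr::pull(data, !!wq)

  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (!is.null(wv)) wv <- wv[ok]
  n <- length(xv)
  if (n < 3) {
    stop("need at least 3 paired observations (got ", n, ")", call. = FALSE)
  }
  if (stats::var(xv) == 0) {
    stop("degenerate covariate: x is constant", call. = FALSE)
  }

  df <- data.frame(.x = xv, .y = yv)
  fit <- if (is.null(wv)) {
    stats::lm(.y ~ .x, data = df)
  } else {
    stats::lm(.y ~ .x, data = df, weights = wv)
  }
  coefs <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  w <- wv %||% rep(1, n)
  ss_res <- sum(w * stats::residuals(fit)^2)
  ss_reg <- sum(w * (fitted - stats::weighted.mean(yv, w))^2)
  ss_tot <- ss_reg + ss_res
  scale <- max(sum(w * yv^2), .Machine$double.eps)
  df_den <- n - 2L
  if (ss_tot <= 1e-12 * scale) {
    f_stat <- 0 # y constant: no variance to explain
    p <- 1
    r2 <- 0
    coefs[2L] <- 0
  } else if (ss_res <= 1e-12 * ss_tot) {
    f_stat <- Inf
    p <- 0
    r2 <- 1
  } else {
    f_stat <- (ss_reg / 1) / (ss_res / df_den)
    p <- stats::pf(f_stat, 1, df_den, lower.tail = FALSE)
    r2 <- ss_reg / (ss_reg + ss_res)
  }
  out <- tibble::tibble(
    slope = unname(coefs[2L]),
    intercept = unname(coefs[1L]),
    f_statistic = f_stat,
    p_value = p,
    r_squared = r2,
    df_num = 1L,
    df_den = df_den,
    n = n
  )
  attr(out, "fit") <- fit
  out
}
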