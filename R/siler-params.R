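#' Siler hazard parameters
#'
#' Bundles the five hazard parameters of the Siler competing-hazard model
#' together with the frequency amplitude `a` and residual standard deviation
#' `sigma` used by the observation model. All rates are per year.
#'
#' The hazard is the sum of up to three components:
#' \deqn{\mu(x) = a_1 e^{-b_1 x} + a_2 + a_3 e^{b_3 x}}
#' where `a1` is the initial maturation (juvenile) hazard and `b1` its decay
#' rate, `a2` the age-independent hazard, and `a3` the initial senescence
#' hazard with exponential growth rate `b3`.
#'
#' @param a1 Initial maturation hazard (per year), `>= 0`.
#' @param b1 Decay rate of the maturation hazard (per year), `>= 0`. A value
#'   of 0 is interpreted as the analytic limit in which the maturation
#'   component reduces to a constant hazard `a1`.
#' @param a2 Constant hazard (per year), `>= 0`.
#' @param a3 Initial senescence hazard (per year), `>= 0`.
#' @param b3 Growth rate of the senescence hazard (per year), `>= 0`; 0 is
#'   again the constant-hazard limit.
#' @param a Amplitude scaling expected age frequencies; same units as the
#'   observed frequencies (proportions or counts), `>= 0`.
#' @param sigma Residual standard deviation of the observed frequencies,
#'   `>= 0`.
#'
#' @return An object of class `siler_params` (a named list).
#' @export
#' @examples
#' siler_params(a2 = -log(0.65)) # constant annual survival of 0.65
siler_params <- function(a1 = 0, b1 = 0, a2 = 0, a3 = 0, b3 = 0,
                         a = 1, sigma = 0) {
  p <- list(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3,
            a = a, sigma = sigma)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) {
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
    }
  }
  structure(p, class = "siler_params")
}

#' @export
print.siler_params <- function(x, ...) {
  cat("Siler parameters (per year):\n")
  cat(sprintf("  maturation a1 = %g, b1 = %g\n", x$a1, x$b1))
  cat(sprintf("  constant   a2 = %g\n", x$a2))
  cat(sprintf("  senescence a3 = %g, b3 = %g\n", x$a3, x$b3))
  cat(sprintf("  amplitude a = %g, residual sigma = %g\n", x$a, x$sigma))
  invisible(x)
}

#' Coerce named input (vector or list) to siler_params, filling zeros
#' @noRd
as_siler_params <- function(params) {
  if (inherits(params, "siler_params")) {
    return(params)
  }
  if (is.numeric(params) && !is.null(names(params))) {
    params <- as.list(params)
  }
  if (!is.list(params) || is.null(names(params))) {
    stop("params must be a siler_params object or a named vector/list",
         call. = FALSE)
  }
  known <- c("a1", "b1", "a2", "a3", "b3", "a", "sigma")
  bad <- setdiff(names(params), known)
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(siler_params, params)
}
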