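#' Subdiffusion parameter pair
#'
#' Bundles the anomalous-diffusion exponent \code{alpha} and the generalized
#' diffusion coefficient \code{k_alpha} together with the derived series
#' exponents \code{beta = alpha/2 - 1}, \code{gamma = alpha/2} and the Hurst
#' exponent \code{H = alpha/2}.  The admissible range for a fractional
#' diffusion equation is \code{0 < alpha < 2}; \code{alpha = 1} is ordinary
#' (Gaussian) diffusion, \code{alpha < 1} subdiffusion with a fat-tailed
#' propagator.
#'
#' @param alpha anomalous-diffusion exponent, in (0, 2).
#' @param k_alpha generalized diffusion coefficient, in squared value units
#'   per time unit to the power \code{alpha} (here: (1/Ohm)^2 per 31-day
#'   registration period^alpha); must be positive.
#' @return An object of class \code{"fractional_params"}: a list with fields
#'   \code{alpha}, \code{k_alpha}, \code{beta}, \code{gamma}, \code{hurst}.
#' @examples
#' p <- fractional_params(0.47, 1)
#' p$hurst  # 0.235
#' @export
fractional_params <- function(alpha, k_alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 2)
    stop("'alpha' must be a single finite number in (0, 2), got ",
         format(alpha), call. = FALSE)
  if (!is.numeric(k_alpha) || length(k_alpha) != 1L || !is.finite(k_alpha) ||
      k_alpha <= 0)
    stop("'k_alpha' must be a single positive finite number", call. = FALSE)
  structure(
    list(alpha = alpha, k_alpha = k_alpha,
         beta = alpha / 2 - 1, gamma = alpha / 2, hurst = alpha / 2),
    class = "fractional_params")
}

#' @export
print.fractional_params <- function(x, ...) {
  cat(sprintf(
    "Fractional diffusion parameters: alpha = %g, K_alpha = %g\n", x$alpha,
    x$k_alpha))
  cat(sprintf("  beta = %g, gamma = %g, Hurst H = %g\n",
              x$beta, x$gamma, x$hurst))
  invisible(x)
}

#' Series exponents derived from alpha
#'
#' @param params a \code{\link{fractional_params}} object.
#' @return Named numeric vector \code{c(beta = alpha/2 - 1, gamma = alpha/2)}.
#' @export
derived_exponents <- function(params) {
  stopifnot(inherits(params, "fractional_params"))
  c(beta = params$beta, gamma = params$gamma)
}

#' Hurst exponent of a subdiffusive process
#'
#' For mean squared displacement growing as \code{t^alpha} the Hurst exponent
#' is \code{H = alpha/2}; \code{H = 1/2} is classical Brownian scaling, and
#' \code{H < 1/2} signals the fat-tailed, subdiffusive regime.
#'
#' @param alpha anomalous-diffusion exponent(s) in (0, 2).
#' @return \code{alpha / 2}.
#' @export
hurst <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha <= 0) || any(alpha >= 2))
    stop("'alpha' must lie strictly inside (0, 2)", call. = FALSE)
  alpha / 2
}

# non-throwing range check used by the fitting grid
is_valid_pair <- function(alpha, k_alpha) {
  is.finite(alpha) && alpha > 0 && alpha < 2 && is.finite(k_alpha) &&
    k_alpha > 0
}
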