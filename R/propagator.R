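#' Numerical settings for propagator evaluation
#'
#' The propagator is evaluated from its power series in the similarity
#' variable \code{xi = g / t^gamma}.  The series is alternating: for large
#' \code{xi} (or \code{alpha} close to 2) cancellation destroys double
#' precision, so evaluation switches to a fixed-Talbot numerical inverse
#' Laplace transform.  The switch happens when \code{xi} exceeds
#' \code{regime_threshold}, when the series has not converged after
#' \code{k_max} terms, or when the cancellation guard
#' \code{max|term| * eps / |sum|} exceeds \code{cancel_tol}.
#'
#' @param k_max maximum series index (>= 1).
#' @param term_tol absolute truncation tolerance; summation stops after four
#'   consecutive terms below it (single small terms can be spurious zeros of
#'   the reciprocal Gamma function).
#' @param regime_threshold cutover value of \code{g / t^gamma} above which
#'   the Talbot evaluator is used directly.
#' @param cancel_tol maximum tolerated ratio of rounding noise to the summed
#'   value before falling back to the Talbot evaluator.
#' @param talbot_nodes number of nodes of the fixed-Talbot contour (>= 32).
#' @param allow_fallback if \code{FALSE}, a series failure raises an error
#'   (of class \code{"anomdiff_series_error"}, carrying the partial sum and
#'   the last term magnitude) instead of switching evaluators.
#' @return A list of class \code{"series_settings"}.
#' @export
series_settings <- function(k_max = 250L, term_tol = 1e-14,
                            regime_threshold = 5, cancel_tol = 1e-8,
                            talbot_nodes = 32L, allow_fallback = TRUE) {
  stopifnot(k_max >= 1, term_tol > 0, regime_threshold > 0, cancel_tol > 0,
            talbot_nodes >= 32)
  structure(list(k_max = as.integer(k_max), term_tol = term_tol,
                 regime_threshold = regime_threshold,
                 cancel_tol = cancel_tol,
                 talbot_nodes = as.integer(talbot_nodes),
                 allow_fallback = isTRUE(allow_fallback)),
            class = "series_settings")
}

# Reciprocal Gamma function, entire: zero at the poles of Gamma
# (non-positive integers).  Returns log-magnitude and sign so callers can
# combine exponents before exponentiating.
recip_gamma_log <- function(x) {
  if (x >= 0.5) return(c(lmag = -lgamma(x), sign = 1))
  if (x <= 0 && abs(x - round(x)) < 1e-12) return(c(lmag = -Inf, sign = 0))
  # reflection: 1/Gamma(x) = sin(pi x) Gamma(1 - x) / pi
  s <- sinpi(x)
  c(lmag = log(abs(s)) + lgamma(1 - x) - log(pi), sign = sign(s))
}

#' Reciprocal Gamma function
#'
#' \code{1/Gamma(x)}, evaluated as an entire function: exactly zero at the
#' poles of Gamma (x = 0, -1, -2, ...), via the reflection formula for
#' negative arguments.
#'
#' @param x numeric vector.
#' @return \code{1/Gamma(x)} with zeros at non-positive integers.
#' @export
recip_gamma <- function(x) {
  vapply(x, function(xi) {
    lg <- recip_gamma_log(xi)
    lg[["sign"]] * exp(lg[["lmag"]])
  }, numeric(1))
}

# Core series: S(xi) = sum_k rgamma(-k*gamma - beta) (-xi)^k / k!
# Vectorized over xi.  Returns sum, convergence flag, cancellation guard.
series_sum <- function(xi, beta, gamma, k_max, term_tol) {
  n <- length(xi)
  lxi <- ifelse(xi > 0, log(xi), -Inf)
  total <- numeric(n)
  comp <- numeric(n)         # Kahan compensation
  maxterm <- numeric(n)
  nsmall <- integer(n)
  active <- rep(TRUE, n)
  k <- 0L
  while (k <= k_max && any(active)) {
    rg <- recip_gamma_log(-k * gamma - beta)
    if (rg[["sign"]] != 0) {
      sgn <- rg[["sign"]] * (1 - 2 * (k %% 2L))
      if (k == 0L) {
        term <- rep(sgn * exp(rg[["lmag"]]), n)
      } else {
        term <- sgn * exp(rg[["lmag"]] + k * lxi - lgamma(k + 1))
      }
    } else {
      term <- numeric(n)     # pole of Gamma: the term is exactly zero
    }
    ia <- which(active)
    y <- term[ia] - comp[ia]
    tt <- total[ia] + y
    comp[ia] <- (tt - total[ia]) - y
    total[ia] <- tt
    maxterm[ia] <- pmax(maxterm[ia], abs(term[ia]))
    nsmall[ia] <- ifelse(abs(term[ia]) < term_tol, nsmall[ia] + 1L, 0L)
    active[ia] <- !(nsmall[ia] >= 4L & k >= 3L) & is.finite(total[ia])
    k <- k + 1L
  }
  converged <- nsmall >= 4L & is.finite(total)
  guard <- maxterm * .Machine$double.eps /
    pmax(abs(total), .Machine$double.xmin)
  list(sum = total, converged = converged, guard = guard,
       last_k = k - 1L, maxterm = maxterm)
}

# stretched-exponential decay exponent Y(xi) = c(gamma) * xi^(1/(1-gamma))
# of the similarity function, c = (1-gamma) * gamma^(gamma/(1-gamma))
tail_exponent <- function(xi, gamma) {
  (1 - gamma) * gamma^(gamma / (1 - gamma)) * xi^(1 / (1 - gamma))
}

# Saddle-point asymptotic of the similarity function for large xi (the
# M-Wright large-argument expansion):
#   f ~ t^(-(1+beta)) * C * xi^p * exp(-Y(xi)),
#   p = (2 gamma - 1)/(2 - 2 gamma),  C = gamma^p / sqrt(2 pi (1 - gamma)).
# At gamma = 1/2 this is the exact Gaussian; relative accuracy is O(1/Y).
asymptotic_f <- function(t, g, gamma) {
  xi <- g * t^(-gamma)
  p <- (2 * gamma - 1) / (2 - 2 * gamma)
  C <- gamma^p / sqrt(2 * pi * (1 - gamma))
  lv <- log(C) + p * log(xi) - tail_exponent(xi, gamma) - (1 - gamma) * log(t)
  exp(lv)   # underflows to exact zero deep in the tail
}

# Fixed-Talbot inverse Laplace transform of F(s) = s^(gamma-1) exp(-g s^gamma),
# which is the Laplace image (in t) of the similarity function f_{beta,gamma}
# with beta = gamma - 1.  Vectorized over g; M nodes on the Talbot contour.
# In double precision the contour is accurate (~1e-10 relative) while the
# decay exponent Y stays moderate; far in the tail (large Y) it degrades
# and, for gamma > 1/2, eventually overflows, so callers switch to
# asymptotic_f there.
talbot_f <- function(t, g, gamma, nodes = 32L) {
  stopifnot(t > 0, all(g >= 0), gamma > 0, gamma < 1)
  M <- as.integer(nodes)
  r <- 2 * M / (5 * t)
  th <- pi * seq_len(M - 1L) / M
  cot <- cos(th) / sin(th)
  s <- r * th * complex(real = cot, imaginary = 1)      # contour nodes
  sig <- th + (th * cot - 1) * cot
  w <- exp(t * s) * s^(gamma - 1) * complex(real = 1, imaginary = sig)
  E <- exp(-outer(g, s^gamma))                          # |g| x (M-1)
  tot <- as.vector(Re(E %*% w))
  tot <- tot + 0.5 * exp(r * t) * r^(gamma - 1) * exp(-g * r^gamma)
  out <- tot * r / M
  if (any(!is.finite(out)))
    stop("Talbot contour evaluation failed (non-finite result)",
         call. = FALSE)
  out
}

# out-of-series-regime evaluator: Talbot while the decay exponent is
# moderate (Y <= 13, contour reliable), saddle-point asymptotic beyond
fallback_f <- function(t, g, gamma, nodes = 32L) {
  xi <- g * t^(-gamma)
  Y <- tail_exponent(xi, gamma)
  out <- numeric(length(g))
  near <- Y <= 13
  if (any(near)) out[near] <- talbot_f(t, g[near], gamma, nodes)
  if (any(!near)) out[!near] <- asymptotic_f(t, g[!near], gamma)
  out
}

#' Similarity function of the subdiffusive propagator
#'
#' Evaluates \deqn{f_{\beta,\gamma}(t, g) = t^{-(1+\beta)} \sum_{k \ge 0}
#' \frac{1}{k!\,\Gamma(-k\gamma - \beta)} (-g t^{-\gamma})^k,}
#' the one-sided similarity form of the fractional-diffusion Green's
#' function, with \code{beta = alpha/2 - 1} and \code{gamma = alpha/2}.
#' Terms whose Gamma argument hits a pole contribute exactly zero (the
#' reciprocal Gamma function is entire).  Summation is compensated (Kahan);
#' outside the series' reliable regime evaluation falls back to a
#' fixed-Talbot inverse Laplace transform of
#' \code{s^(gamma-1) exp(-g s^gamma)} and the result is flagged.
#'
#' @param t elapsed time, a single positive number.
#' @param g nonnegative similarity argument(s), \code{|x - x0| / sqrt(K_alpha)}.
#' @param beta,gamma series exponents; \code{beta = gamma - 1} is required.
#' @param settings a \code{\link{series_settings}} object.
#' @return Numeric vector of values of \code{f}; attribute \code{"fallback"}
#'   is a logical vector marking components computed by Talbot inversion.
#' @examples
#' series_f(1, 0, -0.5, 0.5)   # Gaussian case: 1/sqrt(pi)
#' @export
series_f <- function(t, g, beta, gamma, settings = series_settings()) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive number", call. = FALSE)
  if (any(!is.finite(g)) || any(g < 0))
    stop("'g' must be finite and nonnegative", call. = FALSE)
  if (abs(beta - (gamma - 1)) > 1e-12)
    stop("'beta' must equal 'gamma' - 1", call. = FALSE)
  if (gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie in (0, 1)", call. = FALSE)
  xi <- g * t^(-gamma)
  pref <- t^(-(1 + beta))
  out <- numeric(length(g))
  fallback <- xi > settings$regime_threshold
  idx <- which(!fallback)
  if (length(idx)) {
    ss <- series_sum(xi[idx], beta, gamma, settings$k_max, settings$term_tol)
    bad <- !ss$converged | ss$guard > settings$cancel_tol
    if (any(bad) && !settings$allow_fallback) {
      b <- idx[which(bad)[1L]]
      cond <- structure(
        class = c("anomdiff_series_error", "error", "condition"),
        list(message = sprintf(
               paste0("propagator series did not converge at g = %g ",
                      "(partial sum %g, max term %g); fallback disabled"),
               g[b], pref * ss$sum[which(bad)[1L]],
               ss$maxterm[which(bad)[1L]]),
             call = sys.call(-1),
             partial_sum = pref * ss$sum[which(bad)[1L]],
             max_term = ss$maxterm[which(bad)[1L]]))
      stop(cond)
    }
    out[idx] <- pref * ss$sum
    fallback[idx[bad]] <- TRUE
  }
  if (any(fallback)) {
    if (!settings$allow_fallback)
      stop("similarity argument outside the series regime and fallback ",
           "disabled", call. = FALSE)
    out[fallback] <- fallback_f(t, g[fallback], gamma, settings$talbot_nodes)
  }
  attr(out, "fallback") <- fallback
  out
}

#' Propagator evaluation query
#'
#' Validates an evaluation point of the propagator and computes the
#' similarity argument \code{g = |x - x0| / sqrt(K_alpha)}.
#'
#' @param x evaluation point(s) (value units, 1/Ohm).
#' @param x0 initial point (value units).
#' @param t elapsed time in registration periods (31 days); positive.
#' @param params a \code{\link{fractional_params}} object.
#' @return List of class \code{"propagator_query"} with \code{x, x0, t, g}.
#' @export
propagator_query <- function(x, x0, t, params) {
  stopifnot(inherits(params, "fractional_params"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive time", call. = FALSE)
  if (any(!is.finite(x)) || !is.finite(x0))
    stop("'x' and 'x0' must be finite", call. = FALSE)
  structure(list(x = x, x0 = x0, t = t,
                 g = abs(x - x0) / sqrt(params$k_alpha)),
            class = "propagator_query")
}

#' Subdiffusive propagator (Green's function) of the fractional diffusion
#' equation
#'
#' Free-space solution density at \code{x} and time \code{t} for a process
#' started at \code{x0}:
#' \deqn{P(x, t; x_0) = \frac{1}{2\sqrt{K_\alpha}}
#'   f_{\beta,\gamma}\!\left(t, \frac{|x - x_0|}{\sqrt{K_\alpha}}\right),}
#' normalized to unit mass and reducing exactly to the Gaussian kernel at
#' \code{alpha = 1}.
#'
#' @param x evaluation point(s), or a \code{\link{propagator_query}}.
#' @param t elapsed time (periods); ignored when \code{x} is a query.
#' @param params a \code{\link{fractional_params}} object.
#' @param x0 initial point; ignored when \code{x} is a query.
#' @param settings a \code{\link{series_settings}} object.
#' @return Density values (per value unit), with attribute \code{"fallback"}.
#' @examples
#' p <- fractional_params(1, 1)
#' evaluate_propagator(0, 1, p)   # 1/sqrt(4*pi)
#' @export
evaluate_propagator <- function(x, t = NULL, params, x0 = 0,
                                settings = series_settings()) {
  q <- if (inherits(x, "propagator_query")) x else propagator_query(x, x0, t, params)
  f <- series_f(q$t, q$g, params$beta, params$gamma, settings)
  out <- f / (2 * sqrt(params$k_alpha))
  attr(out, "fallback") <- attr(f, "fallback")
  out
}

#' Gaussian (alpha = 1) limit of the propagator
#'
#' Closed form \code{1/sqrt(4 pi k t) * exp(-(x - x0)^2 / (4 k t))}; the
#' analytic oracle for the ordinary-diffusion limit.
#'
#' @param x evaluation point(s).
#' @param t positive time.
#' @param k diffusion coefficient (> 0).
#' @param x0 initial point.
#' @return Density values.
#' @export
gaussian_limit_propagator <- function(x, t, k, x0 = 0) {
  stopifnot(t > 0, k > 0)
  stats::dnorm(x, mean = x0, sd = sqrt(2 * k * t))
}

#' Propagator by numerical inverse Laplace transform
#'
#' Independent route to the propagator: the Laplace-domain representation
#' \code{P(x, s) = s^(alpha/2 - 1) / (2 sqrt(K_alpha)) *
#' exp(-|x - x0| s^(alpha/2) / sqrt(K_alpha))} inverted on the fixed-Talbot
#' contour.  Serves as the cross-check oracle for the series evaluator.
#'
#' @param x evaluation point(s).
#' @param t positive time.
#' @param params a \code{\link{fractional_params}} object.
#' @param x0 initial point.
#' @param nodes number of Talbot nodes (>= 32).
#' @return Density values.
#' @export
laplace_oracle <- function(x, t, params, x0 = 0, nodes = 32L) {
  stopifnot(inherits(params, "fractional_params"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a single positive time", call. = FALSE)
  g <- abs(x - x0) / sqrt(params$k_alpha)
  talbot_f(t, g, params$gamma, nodes) / (2 * sqrt(params$k_alpha))
}

#' Mean squared displacement of the subdiffusive process
#'
#' Closed form \code{<x^2(t)> = 2 K_alpha t^alpha / Gamma(1 + alpha)}: the
#' power-law growth of variance whose exponent defines the process (slope
#' \code{alpha} on a log-log plot; Hurst exponent \code{alpha/2}).
#'
#' @param params a \code{\link{fractional_params}} object.
#' @param t positive time(s).
#' @return Second central moment(s) of the propagator.
#' @examples
#' msd(fractional_params(1, 1), 2)   # classical 2 K t = 4
#' @export
msd <- function(params, t) {
  stopifnot(inherits(params, "fractional_params"))
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  2 * params$k_alpha * t^params$alpha / gamma(1 + params$alpha)
}

#' Admissibility check of a parameter pair
#'
#' A pair (alpha, K_alpha) is admissible when the evaluated solution behaves
#' as a proper probability density over the region of interest:
#' nonnegative everywhere on the grid, unit mass under quadrature at every
#' tested time, and -- when slot edges are supplied -- per-slot probability
#' masses at most 1.  The upper bound is checked on slot masses, not on raw
#' density values: a perfectly valid density exceeds 1 whenever its scale
#' parameter is small (a Gaussian with \code{4 K t < 1/pi} does).
#'
#' @param params a \code{\link{fractional_params}} object (its construction
#'   already rejects \code{alpha} outside (0, 2) and nonpositive
#'   \code{k_alpha}).
#' @param x_grid nonempty numeric vector of evaluation points.
#' @param t_grid nonempty vector of positive times.
#' @param x0 initial point.
#' @param slot_edges optional strictly increasing slot edges on which
#'   per-slot masses are checked.
#' @param settings a \code{\link{series_settings}} object.
#' @return List of class \code{"admissibility_report"} with fields
#'   \code{admissible}, \code{nonneg_ok}, \code{normalized_ok},
#'   \code{slot_mass_ok}, \code{density_min}, \code{density_max},
#'   \code{norm_error} (per time), \code{reasons}.
#' @export
check_admissibility <- function(params, x_grid, t_grid, x0 = 0,
                                slot_edges = NULL,
                                settings = series_settings()) {
  stopifnot(inherits(params, "fractional_params"))
  if (length(x_grid) == 0L || length(t_grid) == 0L)
    stop("'x_grid' and 't_grid' must be nonempty", call. = FALSE)
  if (any(t_grid <= 0)) stop("'t_grid' must be positive", call. = FALSE)

  dmin <- Inf; dmax <- -Inf
  norm_err <- numeric(length(t_grid))
  slot_ok <- TRUE
  for (i in seq_along(t_grid)) {
    tt <- t_grid[i]
    v <- evaluate_propagator(x_grid, tt, params, x0, settings)
    dmin <- min(dmin, min(v)); dmax <- max(dmax, max(v))
    half <- 40 * sqrt(msd(params, tt))
    qq <- stats::integrate(
      function(u) evaluate_propagator(u, tt, params, x0, settings),
      lower = x0 - half, upper = x0 + half,
      rel.tol = 1e-6, subdivisions = 400L)
    norm_err[i] <- abs(qq$value - 1)
    if (!is.null(slot_edges)) {
      m <- density_slot_masses(function(u)
        evaluate_propagator(u, tt, params, x0, settings), slot_edges)
      if (any(m > 1 + 1e-9)) slot_ok <- FALSE
    }
  }
  nonneg_ok <- dmin >= -1e-9
  normalized_ok <- all(norm_err <= 1e-3)
  reasons <- character(0)
  if (!nonneg_ok) reasons <- c(reasons, "negative density values on grid")
  if (!normalized_ok)
    reasons <- c(reasons, sprintf("quadrature mass off by up to %.2e",
                                  max(norm_err)))
  if (!slot_ok) reasons <- c(reasons, "a slot probability mass exceeds 1")
  structure(list(admissible = nonneg_ok && normalized_ok && slot_ok,
                 nonneg_ok = nonneg_ok, normalized_ok = normalized_ok,
                 slot_mass_ok = slot_ok, density_min = dmin,
                 density_max = dmax, norm_error = norm_err,
                 alpha = params$alpha, k_alpha = params$k_alpha,
                 reasons = reasons),
            class = "admissibility_report")
}

#' @export
print.admissibility_report <- function(x, ...) {
  cat(sprintf("Admissibility of (alpha = %g, K_alpha = %g): %s\n", x$alpha,
              x$k_alpha, if (x$admissible) "admissible" else "INADMISSIBLE"))
  cat(sprintf("  density range [%.3e, %.3e]; max |mass - 1| = %.2e\n",
              x$density_min, x$density_max, max(x$norm_error)))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "),
                             "\n")
  invisible(x)
}

# integrate a density over each slot [edges[i], edges[i+1])
density_slot_masses <- function(dens, edges) {
  vapply(seq_len(length(edges) - 1L), function(i) {
    stats::integrate(dens, edges[i], edges[i + 1L],
                     rel.tol = 1e-7, subdivisions = 200L)$value
  }, numeric(1))
}
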