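#' Binned probability distribution over value slots
#'
#' A probability mass function over contiguous value slots (by default the
#' 15 TFC slots of the registration protocol).  Slots are half-open
#' \code{[lo, hi)}; the last slot is closed.
#'
#' @param slot_edges strictly increasing numeric vector of slot boundaries
#'   (length = number of slots + 1).
#' @param masses nonnegative slot masses summing to 1 (within 1e-9 unless
#'   \code{normalize = TRUE}, in which case any nonnegative, non-degenerate
#'   vector is rescaled).
#' @param normalize rescale \code{masses} to unit sum instead of requiring it.
#' @return An object of class \code{"binned_distribution"}.
#' @export
binned_distribution <- function(slot_edges, masses, normalize = FALSE) {
  if (!is.numeric(slot_edges) || length(slot_edges) < 2L ||
      any(!is.finite(slot_edges)) || any(diff(slot_edges) <= 0))
    stop("'slot_edges' must be strictly increasing and finite", call. = FALSE)
  if (!is.numeric(masses) || length(masses) != length(slot_edges) - 1L)
    stop("'masses' must have one value per slot (",
         length(slot_edges) - 1L, ")", call. = FALSE)
  if (any(!is.finite(masses)) || any(masses < 0))
    stop("'masses' must be finite and nonnegative", call. = FALSE)
  s <- sum(masses)
  if (normalize) {
    if (s <= 0) stop("cannot normalize all-zero masses", call. = FALSE)
    masses <- masses / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("masses must sum to 1 (got %.12g); use normalize = TRUE", s),
         call. = FALSE)
  }
  structure(list(slot_edges = as.numeric(slot_edges),
                 masses = as.numeric(masses)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  n <- length(x$masses)
  cat(sprintf("Binned distribution: %d slots on [%g, %g]\n", n,
              x$slot_edges[1], x$slot_edges[n + 1]))
  print(round(stats::setNames(
    x$masses, sprintf("%g:%g", x$slot_edges[-(n + 1)], x$slot_edges[-1])), 4))
  invisible(x)
}

slot_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
slot_widths  <- function(edges) diff(edges)

# mean and variance of a binned distribution (slot-center approximation)
binned_moments <- function(d) {
  ctr <- slot_centers(d$slot_edges)
  mu <- sum(ctr * d$masses)
  c(mean = mu, var = sum((ctr - mu)^2 * d$masses))
}

#' Evolve a binned distribution forward in time
#'
#' Propagates an initial binned distribution by the subdiffusive kernel:
#' the continuous superposition \code{P(x, t) = integral of
#' G(x, t; x') p0(x') dx'} discretized either at slot centers (midpoint
#' rule, the fast default) or on a refined grid that is integrated and
#' re-binned (\code{method = "dense"}, the oracle mode).  The value range is
#' physiologically bounded, so kernel mass transported past the outer edges
#' is truncated and the result renormalized to unit mass.
#'
#' @param initial a \code{\link{binned_distribution}}.
#' @param t positive evolution time in registration periods.
#' @param params a \code{\link{fractional_params}} object.
#' @param settings a \code{\link{series_settings}} object.
#' @param method \code{"midpoint"} (slot centers) or \code{"dense"}
#'   (refined grid, used as the internal accuracy oracle).
#' @param refine points per slot for the dense method.
#' @return A \code{\link{binned_distribution}} on the same slot edges.
#' @export
evolve_distribution <- function(initial, t, params,
                                settings = series_settings(),
                                method = c("midpoint", "dense"),
                                refine = 64L) {
  stopifnot(inherits(initial, "binned_distribution"),
            inherits(params, "fractional_params"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive time", call. = FALSE)
  method <- match.arg(method)
  edges <- initial$slot_edges
  if (method == "midpoint") {
    pts <- slot_centers(edges)
    wts <- slot_widths(edges)
    src <- pts
    src_mass <- initial$masses
  } else {
    refine <- as.integer(refine)
    stopifnot(refine >= 2L)
    sub <- unlist(lapply(seq_along(initial$masses), function(j) {
      seq(edges[j], edges[j + 1L],
          length.out = refine + 1L)[-(refine + 1L)] +
        slot_widths(edges)[j] / (2 * refine)
    }))
    pts <- sub
    wts <- rep(slot_widths(edges) / refine, each = refine)
    src <- sub
    # constant density within each slot
    src_mass <- rep(initial$masses / refine, each = refine)
  }
  # kernel depends on |x - x'| only: evaluate on unique distances
  dmat <- abs(outer(pts, src, "-"))
  ud <- unique(signif(as.vector(dmat), 12))
  kv <- series_f(t, ud / sqrt(params$k_alpha), params$beta, params$gamma,
                 settings) / (2 * sqrt(params$k_alpha))
  G <- matrix(kv[match(signif(dmat, 12), ud)], nrow = length(pts))
  dens <- as.vector(G %*% src_mass)
  raw <- dens * wts
  if (any(raw < -1e-6))
    stop("evolved kernel produced substantially negative mass; ",
         "parameter pair behaves inadmissibly", call. = FALSE)
  raw[raw < 0] <- 0
  if (method == "dense") {
    raw <- vapply(split(raw, rep(seq_along(initial$masses), each = refine)),
                  sum, numeric(1))
  }
  binned_distribution(edges, raw, normalize = TRUE)
}

#' Pooled stationary-distribution estimate
#'
#' Pools hit counts across all registration periods and normalizes by the
#' grand total; the empirical counterpart of the stationary TFC
#' distribution the registration protocol converges to.
#'
#' @param obs a \code{\link{binned_observations}} object.
#' @return A \code{\link{binned_distribution}} on the observation slot edges.
#' @export
stationary_estimate <- function(obs) {
  stopifnot(inherits(obs, "binned_observations"))
  pooled <- colSums(obs$counts)
  if (sum(pooled) <= 0)
    stop("cannot estimate a distribution from all-zero counts",
         call. = FALSE)
  binned_distribution(obs$slot_edges, pooled / sum(pooled))
}

#' Total-variation distance between binned distributions
#'
#' \code{0.5 * sum(|a_i - b_i|)}, in [0, 1]; the stationarity diagnostic for
#' comparing per-period distributions.
#'
#' @param a,b \code{\link{binned_distribution}} objects on identical edges.
#' @return A number in [0, 1].
#' @export
distribution_distance <- function(a, b) {
  stopifnot(inherits(a, "binned_distribution"),
            inherits(b, "binned_distribution"))
  if (length(a$slot_edges) != length(b$slot_edges) ||
      any(abs(a$slot_edges - b$slot_edges) > 1e-9))
    stop("distributions are binned on different slot edges", call. = FALSE)
  0.5 * sum(abs(a$masses - b$masses))
}
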