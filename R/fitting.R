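#' Fitting configuration
#'
#' Controls the RMSE grid search for (alpha, K_alpha).  The search is a
#' coarse grid (alpha linear, K log-spaced) followed by optional Nelder-Mead
#' refinement in transformed coordinates.  The evolved model distribution is
#' scored against observed slot frequencies either at the final registration
#' period only (\code{target = "final_period"}, evaluated at
#' \code{horizon_t}) or jointly against every period
#' (\code{target = "all_periods"}).
#'
#' @param alpha_grid strictly increasing values inside (0, 2).
#' @param k_grid strictly increasing positive values (log-spaced by default).
#' @param refine run local Nelder-Mead refinement from the grid optimum.
#' @param horizon_t evaluation time in periods for the final-period target
#'   (default 5, the five-month registration window).
#' @param target which observed frequencies to fit.
#' @param initial starting distribution: the pooled stationary estimate or
#'   the first period's frequencies.
#' @param trace keep the full grid search trace in the result.
#' @return A list of class \code{"fit_config"}.
#' @export
fit_config <- function(alpha_grid = seq(0.05, 1.95, by = 0.05),
                       k_grid = 10^seq(-2, 2, length.out = 41L),
                       refine = TRUE, horizon_t = 5,
                       target = c("final_period", "all_periods"),
                       initial = c("stationary", "first_period"),
                       trace = FALSE) {
  if (length(alpha_grid) == 0L || any(diff(alpha_grid) <= 0) ||
      any(alpha_grid <= 0) || any(alpha_grid >= 2))
    stop("'alpha_grid' must be strictly increasing inside (0, 2)",
         call. = FALSE)
  if (length(k_grid) == 0L || any(diff(k_grid) <= 0) || any(k_grid <= 0))
    stop("'k_grid' must be strictly increasing and positive", call. = FALSE)
  stopifnot(horizon_t > 0)
  structure(list(alpha_grid = alpha_grid, k_grid = k_grid,
                 refine = isTRUE(refine), horizon_t = horizon_t,
                 target = match.arg(target), initial = match.arg(initial),
                 trace = isTRUE(trace)),
            class = "fit_config")
}

#' Root-mean-square error between binned distributions
#'
#' \code{sqrt(mean((model_i - observed_i)^2))} over slot masses -- the
#' fitting criterion for matching the theoretical fat-tail distribution to
#' observed slot frequencies.  Computed on normalized masses, so typical
#' good-fit values are of order 1e-3.
#'
#' @param model,observed \code{\link{binned_distribution}} objects on
#'   identical slot edges.
#' @return Nonnegative scalar.
#' @export
rmse <- function(model, observed) {
  stopifnot(inherits(model, "binned_distribution"),
            inherits(observed, "binned_distribution"))
  if (length(model$slot_edges) != length(observed$slot_edges) ||
      any(abs(model$slot_edges - observed$slot_edges) > 1e-9))
    stop("distributions are binned on different slot edges", call. = FALSE)
  sqrt(mean((model$masses - observed$masses)^2))
}

# period-p frequencies as a binned_distribution (p counts row must be nonzero)
period_distribution <- function(obs, p) {
  cnt <- obs$counts[p, ]
  if (sum(cnt) <= 0)
    stop(sprintf("period %d has no hits", p), call. = FALSE)
  binned_distribution(obs$slot_edges, cnt / sum(cnt))
}

# objective pieces: times at which to evolve and which periods to compare
fit_plan <- function(obs, config) {
  np <- nrow(obs$counts)
  init <- switch(config$initial,
                 stationary   = stationary_estimate(obs),
                 first_period = period_distribution(obs, 1L))
  offset <- if (config$initial == "first_period") 1 else 0
  if (config$target == "final_period") {
    if (np < 2L)
      stop("final-period fitting needs at least 2 registration periods",
           call. = FALSE)
    times <- config$horizon_t - offset
    targets <- list(period_distribution(obs, np))
  } else {
    ps <- if (config$initial == "first_period") seq(2L, np) else seq_len(np)
    times <- ps - offset
    targets <- lapply(ps, period_distribution, obs = obs)
  }
  if (any(times <= 0))
    stop("evolution times must be positive; lower 'horizon_t' offset",
         call. = FALSE)
  list(init = init, times = times, targets = targets)
}

# joint RMSE of one parameter pair under a fit plan; NA if evolution fails
score_pair <- function(alpha, k_alpha, plan, settings) {
  if (!is_valid_pair(alpha, k_alpha)) return(NA_real_)
  params <- fractional_params(alpha, k_alpha)
  sq <- 0; n <- 0L
  for (i in seq_along(plan$times)) {
    m <- tryCatch(
      evolve_distribution(plan$init, plan$times[i], params, settings),
      error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    sq <- sq + sum((m$masses - plan$targets[[i]]$masses)^2)
    n <- n + length(m$masses)
  }
  sqrt(sq / n)
}

#' Fit subdiffusion parameters to binned observations
#'
#' Estimates (alpha, K_alpha) by minimizing the RMSE between the evolved
#' model distribution and observed slot frequencies, and reports the Hurst
#' exponent H = alpha/2.  Grid pairs outside the admissible range, or whose
#' evolution fails numerically, are skipped and logged.  Ties are broken
#' toward smaller alpha, then smaller K_alpha.  The returned pair is
#' subjected to a full admissibility check (nonnegativity, unit mass, slot
#' masses at most 1).
#'
#' @param obs a \code{\link{binned_observations}} object.
#' @param config a \code{\link{fit_config}} object.
#' @param settings a \code{\link{series_settings}} object.
#' @return List of class \code{"fit_result"}: \code{alpha}, \code{k_alpha},
#'   \code{hurst}, \code{rmse}, \code{admissible}, \code{n_evaluations},
#'   \code{skipped} (count of rejected grid pairs), \code{search_trace}
#'   (data frame, if requested).
#' @export
fit_params <- function(obs, config = fit_config(),
                       settings = series_settings()) {
  stopifnot(inherits(obs, "binned_observations"),
            inherits(config, "fit_config"))
  plan <- fit_plan(obs, config)
  n_eval <- 0L
  grid <- expand.grid(k_alpha = config$k_grid, alpha = config$alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("alpha", "k_alpha")]
  scores <- vapply(seq_len(nrow(grid)), function(i)
    score_pair(grid$alpha[i], grid$k_alpha[i], plan, settings),
    numeric(1))
  n_eval <- n_eval + nrow(grid)
  skipped <- sum(is.na(scores))
  skip_reasons <- if (skipped)
    sprintf("(%g, %g): evolution failed or invalid",
            grid$alpha[is.na(scores)], grid$k_alpha[is.na(scores)])
  else character(0)
  if (all(is.na(scores)))
    stop("no admissible (alpha, K_alpha) pair could be scored; reasons:\n",
         paste(utils::head(skip_reasons, 10L), collapse = "\n"),
         call. = FALSE)
  full_check <- function(alpha, k) {
    ctr <- slot_centers(obs$slot_edges)
    tryCatch(
      check_admissibility(
        fractional_params(alpha, k),
        x_grid = seq(min(ctr), max(ctr), length.out = 41L),
        t_grid = unique(plan$times),
        x0 = stats::weighted.mean(ctr, plan$init$masses),
        slot_edges = obs$slot_edges, settings = settings),
      error = function(e) structure(
        list(admissible = FALSE, nonneg_ok = NA, normalized_ok = NA,
             slot_mass_ok = NA, density_min = NA_real_,
             density_max = NA_real_, norm_error = NA_real_,
             alpha = alpha, k_alpha = k,
             reasons = paste("evaluation failed:", conditionMessage(e))),
        class = "admissibility_report"))
  }
  # candidates in score order; ties broken toward smaller alpha, then K.
  # The returned pair must pass the full admissibility check.
  ord <- order(scores, grid$alpha, grid$k_alpha, na.last = TRUE)
  best <- NULL; rep_adm <- NULL
  for (i in utils::head(ord, 10L)) {
    if (is.na(scores[i])) break
    rep_i <- full_check(grid$alpha[i], grid$k_alpha[i])
    if (rep_i$admissible) {
      best <- list(alpha = grid$alpha[i], k = grid$k_alpha[i],
                   rmse = scores[i])
      rep_adm <- rep_i
      break
    }
    skipped <- skipped + 1L
    skip_reasons <- c(skip_reasons,
                      sprintf("(%g, %g): %s", grid$alpha[i],
                              grid$k_alpha[i],
                              paste(rep_i$reasons, collapse = "; ")))
  }
  if (is.null(best))
    stop("no grid optimum passed the admissibility check; reasons:\n",
         paste(utils::tail(skip_reasons, 10L), collapse = "\n"),
         call. = FALSE)
  if (config$refine) {
    # Nelder-Mead in unconstrained coordinates:
    # alpha = 2/(1 + exp(-u)), K = exp(v)
    obj <- function(par) {
      a <- 2 / (1 + exp(-par[1]))
      k <- exp(par[2])
      n_eval <<- n_eval + 1L
      r <- score_pair(a, k, plan, settings)
      if (is.na(r)) 1e6 else r
    }
    start <- c(log(best$alpha / (2 - best$alpha)), log(best$k))
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 200L, reltol = 1e-8))
    a_ref <- 2 / (1 + exp(-opt$par[1]))
    k_ref <- exp(opt$par[2])
    if (opt$value < best$rmse) {
      rep_ref <- full_check(a_ref, k_ref)
      if (rep_ref$admissible) {   # otherwise keep the checked grid pair
        best <- list(alpha = a_ref, k = k_ref, rmse = opt$value)
        rep_adm <- rep_ref
      }
    }
  }
  structure(list(alpha = best$alpha, k_alpha = best$k,
                 hurst = best$alpha / 2, rmse = best$rmse,
                 admissible = rep_adm$admissible,
                 admissibility = rep_adm,
                 n_evaluations = n_eval, skipped = skipped,
                 search_trace = if (config$trace)
                   data.frame(alpha = grid$alpha[!is.na(scores)],
                              k_alpha = grid$k_alpha[!is.na(scores)],
                              rmse = scores[!is.na(scores)])
                 else NULL,
                 target = config$target, initial = config$initial),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Subdiffusion fit (RMSE criterion)\n")
  cat(sprintf("  alpha   = %.4f\n  K_alpha = %.4g\n  Hurst H = %.4f\n",
              x$alpha, x$k_alpha, x$hurst))
  cat(sprintf("  RMSE    = %.6g over slot masses (%s target, %s start)\n",
              x$rmse, x$target, x$initial))
  cat(sprintf("  admissible pair: %s; %d objective evaluations (%d skipped)\n",
              x$admissible, x$n_evaluations, x$skipped))
  invisible(x)
}
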