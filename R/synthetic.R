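#' Synthetic cohort configuration
#'
#' Describes a synthetic longitudinal cohort with the statistical structure
#' the analysis assumes: a latent continuous-time random walk (CTRW) with
#' Pareto waiting times and Gaussian jumps per patient (subdiffusive for
#' \code{ctrw_alpha < 1}), irregular visit times over the follow-up, values
#' binned into 15 slots, and hits accumulated per 31-day registration
#' period over a 5-period window.  Defaults emulate a cohort of 605
#' heart-failure patients contributing about 2860 TFC measurements over up
#' to 12 months.
#'
#' @param n_patients number of patients.
#' @param follow_up_days per-patient follow-up (372 days, about 12 months).
#' @param visit_rate mean visits per patient over the follow-up (Poisson,
#'   floored at one visit); the default yields about 2860 expected
#'   observations for 605 patients.
#' @param ctrw_alpha waiting-time tail exponent of the latent walk, (0, 2).
#' @param jump_scale standard deviation of one latent jump (value units).
#' @param waiting_scale Pareto scale of the waiting times (days); the
#'   default 0.02 puts latent renewals on the sub-hour scale, so many slot
#'   crossings occur within one 31-day period and the walk is well inside
#'   its scaling regime over the observation window.
#' @param baseline_dist \code{\link{binned_distribution}} of patient initial
#'   values; default is a peaked distribution centered mid-range.
#' @param slot_edges binning edges (default 15 equal slots on [20, 80]).
#' @param period_length_days registration period length (31 days).
#' @param n_periods number of registration periods (5).
#' @param seed root random seed; per-patient streams are derived from it by
#'   fixed offsets, so enlarging the cohort does not reshuffle existing
#'   patients.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_patients = 605L,
                              follow_up_days = 372L,
                              visit_rate = 2860 / 605,
                              ctrw_alpha = 0.8,
                              jump_scale = 0.45,
                              waiting_scale = 0.02,
                              baseline_dist = NULL,
                              slot_edges = seq(20, 80, length.out = 16L),
                              period_length_days = 31L,
                              n_periods = 5L,
                              seed = 1L) {
  stopifnot(n_patients >= 1, follow_up_days >= 1, visit_rate > 0,
            jump_scale >= 0, waiting_scale > 0,
            period_length_days >= 1, n_periods >= 1, length(seed) == 1L)
  if (ctrw_alpha <= 0 || ctrw_alpha >= 2)
    stop("'ctrw_alpha' must lie in (0, 2)", call. = FALSE)
  if (any(diff(slot_edges) <= 0))
    stop("'slot_edges' must be strictly increasing", call. = FALSE)
  if (is.null(baseline_dist)) {
    ctr <- slot_centers(slot_edges)
    w <- stats::dnorm(ctr, mean = mean(range(slot_edges)),
                      sd = diff(range(slot_edges)) / 7.5)
    baseline_dist <- binned_distribution(slot_edges, w, normalize = TRUE)
  }
  stopifnot(inherits(baseline_dist, "binned_distribution"))
  structure(list(n_patients = as.integer(n_patients),
                 follow_up_days = as.integer(follow_up_days),
                 visit_rate = visit_rate, ctrw_alpha = ctrw_alpha,
                 jump_scale = jump_scale, waiting_scale = waiting_scale,
                 baseline_dist = baseline_dist,
                 slot_edges = as.numeric(slot_edges),
                 period_length_days = as.integer(period_length_days),
                 n_periods = as.integer(n_periods),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic per-patient seed derived from the root seed (< 2^31)
patient_seed <- function(seed, i) {
  as.integer((as.double(seed) * 100003 + as.double(i) * 7919) %% 2147483629) + 1L
}

#' Pareto-tailed waiting times
#'
#' Draws i.i.d. waits \code{w = scale * u^(-1/alpha)}, \code{u ~ U(0,1)},
#' with survival \code{P(W > w) = (w/scale)^(-alpha)} for \code{w >= scale}.
#' For \code{alpha <= 1} the mean waiting time diverges, which is what
#' produces subdiffusive scaling of the walk.  Uses the current RNG state.
#'
#' @param n number of waits (>= 1).
#' @param alpha tail exponent in (0, 2).
#' @param scale Pareto scale (minimum wait), positive.
#' @return Vector of \code{n} waits, all \code{>= scale}.
#' @export
sample_waiting_times <- function(n, alpha, scale) {
  stopifnot(n >= 1)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 2)
    stop("'alpha' must lie in (0, 2)", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0)
    stop("'scale' must be positive", call. = FALSE)
  scale * stats::runif(n)^(-1 / alpha)
}

#' Simulate one latent CTRW trajectory
#'
#' Alternates Pareto waits and Gaussian jumps; the value is piecewise
#' constant between renewals and recorded at each renewal.  The trajectory
#' is truncated at the follow-up horizon (the value after the last renewal
#' persists to the horizon).
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param start_value initial value at time 0.
#' @param seed optional seed set before drawing (bit-identical repeats).
#' @return List of class \code{"trajectory"} with \code{times} (days,
#'   starting at 0) and \code{values}; attribute \code{"follow_up_days"}.
#' @export
simulate_trajectory <- function(cfg, start_value, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  times <- 0; values <- start_value
  t_cur <- 0; x_cur <- start_value
  block <- 256L
  while (t_cur <= cfg$follow_up_days) {
    w <- sample_waiting_times(block, cfg$ctrw_alpha, cfg$waiting_scale)
    j <- if (cfg$jump_scale > 0) stats::rnorm(block, 0, cfg$jump_scale)
         else numeric(block)
    tt <- t_cur + cumsum(w)
    xx <- x_cur + cumsum(j)
    keep <- tt <= cfg$follow_up_days
    times <- c(times, tt[keep]); values <- c(values, xx[keep])
    t_cur <- tt[block]; x_cur <- xx[block]
  }
  structure(list(times = times, values = values),
            class = "trajectory",
            follow_up_days = cfg$follow_up_days)
}

# draw one baseline value: slot by mass, uniform within the slot
draw_baseline <- function(bd) {
  j <- sample.int(length(bd$masses), 1L, prob = bd$masses)
  stats::runif(1L, bd$slot_edges[j], bd$slot_edges[j + 1L])
}

#' Simulate a synthetic observation cohort
#'
#' Per patient: an initial value drawn from the baseline distribution
#' (uniform within its slot), a Poisson visit count (floored at 1) with
#' visit times uniform over the follow-up, and recorded values read off the
#' patient's latent CTRW trajectory (last renewal before each visit).
#' Fully deterministic given the config seed.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return Data frame of class \code{"observation_table"} with columns
#'   \code{patient_id}, \code{visit_time_days}, \code{value}.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  out <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seed(cfg$seed, i))
    n_vis <- max(1L, stats::rpois(1L, cfg$visit_rate))
    vt <- sort(stats::runif(n_vis, 0, cfg$follow_up_days))
    start <- draw_baseline(cfg$baseline_dist)
    tr <- simulate_trajectory(cfg, start)
    vals <- tr$values[findInterval(vt, tr$times)]
    out[[i]] <- data.frame(patient_id = i, visit_time_days = vt,
                           value = vals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("observation_table", "data.frame")
  res
}

#' Bin an observation table into periods and value slots
#'
#' Each record with \code{visit_time < n_periods * period_length_days}
#' increments the count of its (period, slot) cell.  Slots are half-open
#' \code{[lo, hi)} with the last slot closed; the period index is
#' \code{floor(visit_time / period_length_days)}.  Values outside the slot
#' range are excluded and reported in the \code{n_overflow} field.
#'
#' @param table an \code{observation_table} (or any data frame with columns
#'   \code{visit_time_days} and \code{value}).
#' @param edges strictly increasing slot edges.
#' @param period_length_days length of one registration period (days).
#' @param n_periods number of periods retained.
#' @return List of class \code{"binned_observations"} with
#'   \code{slot_edges}, \code{period_length_days}, \code{counts}
#'   (\code{n_periods x n_slots} integer matrix) and \code{n_overflow}.
#' @export
bin_observations <- function(table, edges, period_length_days = 31L,
                             n_periods = 5L) {
  stopifnot(is.data.frame(table),
            all(c("visit_time_days", "value") %in% names(table)))
  if (any(diff(edges) <= 0))
    stop("'edges' must be strictly increasing", call. = FALSE)
  n_slots <- length(edges) - 1L
  period <- floor(table$visit_time_days / period_length_days)
  in_window <- period >= 0 & period < n_periods
  slot <- findInterval(table$value, edges, rightmost.closed = TRUE)
  in_range <- slot >= 1L & slot <= n_slots
  keep <- in_window & in_range
  counts <- matrix(0L, nrow = n_periods, ncol = n_slots)
  if (any(keep)) {
    tab <- table(factor(period[keep], levels = 0:(n_periods - 1L)),
                 factor(slot[keep], levels = seq_len(n_slots)))
    counts <- matrix(as.integer(tab), nrow = n_periods)
  }
  structure(list(slot_edges = as.numeric(edges),
                 period_length_days = as.integer(period_length_days),
                 counts = counts,
                 n_overflow = sum(in_window & !in_range)),
            class = "binned_observations")
}

#' @export
print.binned_observations <- function(x, ...) {
  cat(sprintf(
    "Binned observations: %d periods x %d slots (%d-day periods), %d hits",
    nrow(x$counts), ncol(x$counts), x$period_length_days, sum(x$counts)))
  if (x$n_overflow > 0)
    cat(sprintf(", %d out-of-range values excluded", x$n_overflow))
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Ensemble mean squared displacement of simulated trajectories
#'
#' Averages \code{(x(t) - x(0))^2} over trajectories at each requested
#' time, reading the piecewise-constant value at the last renewal before
#' \code{t}.
#'
#' @param trajectories list of \code{\link{simulate_trajectory}} results
#'   (at least 2).
#' @param t_grid times in days, each within every trajectory's follow-up.
#' @return Numeric vector of MSD values, one per time.
#' @export
empirical_msd <- function(trajectories, t_grid) {
  if (length(trajectories) < 2L)
    stop("need at least 2 trajectories", call. = FALSE)
  fu <- min(vapply(trajectories, attr, numeric(1), "follow_up_days"))
  if (any(t_grid > fu))
    stop("'t_grid' exceeds the trajectories' follow-up", call. = FALSE)
  disp2 <- vapply(trajectories, function(tr) {
    idx <- findInterval(t_grid, tr$times)
    (tr$values[idx] - tr$values[1])^2
  }, numeric(length(t_grid)))
  if (length(t_grid) == 1L) mean(disp2) else rowMeans(disp2)
}

# Vectorized CTRW ensemble displacement-squared means for large walker
# counts: cumulative sums via triangular matrix products, walkers processed
# in chunks, blocks extended only for unfinished walkers.
ctrw_ensemble_msd <- function(alpha, waiting_scale, jump_scale, n_walkers,
                              t_grid, seed = 1L, chunk = 20000L,
                              block = 256L) {
  stopifnot(alpha > 0, alpha < 2, waiting_scale > 0, n_walkers >= 2)
  set.seed(seed)
  t_grid <- sort(t_grid)
  t_max <- max(t_grid)
  nt <- length(t_grid)
  U <- upper.tri(matrix(0, block, block), diag = TRUE) * 1  # cumsum operator
  sumsq <- numeric(nt)
  left <- n_walkers
  while (left > 0L) {
    m <- min(chunk, left)
    left <- left - m
    ct <- numeric(m); cx <- numeric(m)
    pos_at <- matrix(0, nt, m)
    done <- rep(FALSE, m)
    while (!all(done)) {
      idx <- which(!done)
      na <- length(idx)
      W <- matrix(waiting_scale * stats::runif(na * block)^(-1 / alpha),
                  na, block)
      CT <- ct[idx] + W %*% U
      J <- cx[idx] + matrix(stats::rnorm(na * block, 0, jump_scale),
                            na, block) %*% U
      for (i in seq_len(nt)) {
        cnt <- rowSums(CT <= t_grid[i])
        upd <- cnt > 0L
        if (any(upd))
          pos_at[i, idx[upd]] <- J[cbind(which(upd), cnt[upd])]
      }
      ct[idx] <- CT[, block]
      cx[idx] <- J[, block]
      done[idx] <- CT[, block] > t_max
    }
    sumsq <- sumsq + rowSums(pos_at^2)
  }
  stats::setNames(sumsq / n_walkers, t_grid)
}

#' CTRW scaling exponent from an ensemble of walkers
#'
#' Simulates \code{n_walkers} latent walks with the config's waiting and
#' jump scales and returns the log-log regression slope of the ensemble MSD
#' over \code{t_grid}; for a subdiffusive walk this estimates
#' \code{ctrw_alpha}.
#'
#' @param cfg a \code{\link{simulation_config}} (its \code{ctrw_alpha},
#'   scales and seed are used).
#' @param n_walkers ensemble size.
#' @param t_grid times in days (default 12 log-spaced points in [10, 300]).
#' @return List with \code{t_grid}, \code{msd} and \code{slope}.
#' @export
ctrw_scaling <- function(cfg, n_walkers = 1e5,
                         t_grid = exp(seq(log(10), log(300),
                                          length.out = 12L))) {
  stopifnot(inherits(cfg, "simulation_config"))
  m <- ctrw_ensemble_msd(cfg$ctrw_alpha, cfg$waiting_scale, cfg$jump_scale,
                         n_walkers, t_grid, seed = cfg$seed)
  fit <- stats::lm(log(m) ~ log(t_grid))
  list(t_grid = t_grid, msd = m,
       slope = unname(stats::coef(fit)[2]))
}
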