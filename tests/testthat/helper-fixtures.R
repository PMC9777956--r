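# shared fixtures built in code

tfc_edges <- function(n_slots = 15L, lo = 20, hi = 80)
  seq(lo, hi, length.out = n_slots + 1L)

# peaked distribution over slots, gaussian-shaped around the range center
peaked_distribution <- function(edges = tfc_edges(), center = NULL, sd = NULL) {
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  if (is.null(center)) center <- mean(range(edges))
  if (is.null(sd)) sd <- diff(range(edges)) / 7.5
  binned_distribution(edges, stats::dnorm(ctr, center, sd), normalize = TRUE)
}

# single-slot point mass
delta_distribution <- function(edges = tfc_edges(), slot = 8L) {
  m <- numeric(length(edges) - 1L)
  m[slot] <- 1
  binned_distribution(edges, m)
}

# binned observations whose period rows are integer-scaled copies of given
# distributions (noiseless pseudo-data for inverse-crime fits)
obs_from_distributions <- function(dists, scale = 1e7) {
  edges <- dists[[1]]$slot_edges
  counts <- do.call(rbind, lapply(dists, function(d) round(d$masses * scale)))
  structure(list(slot_edges = edges, period_length_days = 31L,
                 counts = counts, n_overflow = 0L),
            class = "binned_observations")
}

# small synthetic cohort config for fast tests
small_cohort_config <- function(seed = 1L, ...)
  simulation_config(n_patients = 60L, visit_rate = 8, seed = seed, ...)
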