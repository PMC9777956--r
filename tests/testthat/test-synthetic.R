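test_that("waiting times are Pareto with the configured tail", {
  set.seed(1)
  w <- sample_waiting_times(1e5, 0.8, 2)
  expect_true(all(w >= 2))
  # survival at twice the scale: P(W > 2*scale) = 2^(-alpha)
  p_hat <- mean(w > 4)
  p_true <- 2^(-0.8)
  se <- sqrt(p_true * (1 - p_true) / 1e5)
  expect_lt(abs(p_hat - p_true), 3 * se)
  expect_error(sample_waiting_times(10, 2.5, 1), "0, 2")
  expect_error(sample_waiting_times(10, 0.5, 0), "positive")
})

test_that("heavy-tailed waits have a diverging sample mean for alpha <= 1", {
  grows <- vapply(1:20, function(s) {
    set.seed(s)
    m_small <- mean(sample_waiting_times(1e3, 0.5, 1))
    m_big <- mean(sample_waiting_times(1e6, 0.5, 1))
    m_big > m_small
  }, logical(1))
  expect_gte(mean(grows), 0.95)
})

test_that("trajectories are deterministic, increasing, and truncated", {
  cfg <- small_cohort_config()
  tr1 <- simulate_trajectory(cfg, 50, seed = 11)
  tr2 <- simulate_trajectory(cfg, 50, seed = 11)
  expect_identical(tr1, tr2)
  expect_true(all(diff(tr1$times) > 0))
  expect_lte(max(tr1$times), cfg$follow_up_days)
  expect_identical(tr1$values[1], 50)
  flat <- simulate_trajectory(simulation_config(jump_scale = 0, seed = 1),
                              42, seed = 3)
  expect_true(all(flat$values == 42))
})

test_that("cohorts have the configured size structure", {
  cfg <- simulation_config(seed = 5)   # default: 605 patients, ~2860 obs
  tab <- simulate_cohort(cfg)
  expect_s3_class(tab, "observation_table")
  expect_identical(sort(unique(tab$patient_id)), 1:605)
  expect_true(all(tab$visit_time_days >= 0 &
                  tab$visit_time_days <= cfg$follow_up_days))
  expect_lt(abs(nrow(tab) - 2860) / 2860, 0.05)
  # Poisson mean 1 still guarantees one visit per patient
  tiny <- simulation_config(n_patients = 40, visit_rate = 1, seed = 9)
  t2 <- simulate_cohort(tiny)
  expect_true(all(1:40 %in% t2$patient_id))
})

test_that("identical seed and config give identical cohorts and bins", {
  cfg <- small_cohort_config(seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ba <- bin_observations(a, cfg$slot_edges, cfg$period_length_days,
                         cfg$n_periods)
  bb <- bin_observations(b, cfg$slot_edges, cfg$period_length_days,
                         cfg$n_periods)
  expect_identical(ba, bb)
  # enlarging the cohort does not reshuffle existing patients
  bigger <- small_cohort_config(seed = 21)
  bigger$n_patients <- 80L
  c2 <- simulate_cohort(bigger)
  expect_identical(a, c2[c2$patient_id <= 60, ])
})

test_that("binning follows the half-open slot and floor period rules", {
  tab <- data.frame(patient_id = 1L,
                    visit_time_days = c(0, 30.9, 31, 100, 140, 200),
                    value = c(24, 20, 80, 19, 95, 50))
  edges <- tfc_edges()   # [20, 24) [24, 28) ... [76, 80]
  b <- bin_observations(tab, edges, 31, 5)
  # value 24 at an interior edge goes to the upper slot (slot 2)
  expect_equal(b$counts[1, 2], 1L)
  # day 31 starts the second period; value 80 closes the last slot
  expect_equal(b$counts[2, 15], 1L)
  expect_equal(b$counts[1, 1], 1L)   # value 20, day 30.9, period 1
  # 19 and 95 are in-window but out of range -> overflow, excluded;
  # day 200 falls outside the 5-period window entirely
  expect_equal(b$n_overflow, 2L)
  expect_equal(sum(b$counts), 3L)
  expect_error(bin_observations(tab, c(1, 1, 2)), "increasing")
})

test_that("binned counts conserve in-window records", {
  cfg <- small_cohort_config(seed = 2)
  tab <- simulate_cohort(cfg)
  b <- bin_observations(tab, cfg$slot_edges, 31, 5)
  in_window <- sum(tab$visit_time_days < 5 * 31)
  expect_equal(sum(b$counts) + b$n_overflow, in_window)
})

test_that("empirical MSD is zero for frozen walkers and grows for live ones", {
  cfg <- simulation_config(jump_scale = 0, n_patients = 5, seed = 1)
  frozen <- lapply(1:5, function(i) simulate_trajectory(cfg, 50, seed = i))
  expect_equal(empirical_msd(frozen, c(10, 100, 300)), rep(0, 3),
               ignore_attr = TRUE)
  expect_error(empirical_msd(frozen, 1000), "follow-up")
  expect_error(empirical_msd(frozen[1], 10), "at least 2")

  cfg2 <- simulation_config(ctrw_alpha = 0.5, seed = 4)
  live <- lapply(1:400, function(i)
    simulate_trajectory(cfg2, 0, seed = 1000 + i))
  m <- empirical_msd(live, exp(seq(log(10), log(300), length.out = 10)))
  # smoothed series is non-decreasing within Monte-Carlo noise
  sm <- stats::filter(m, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -0.05 * max(sm)))
})

test_that("ensemble MSD scaling matches the configured exponent", {
  # subdiffusive case at reduced ensemble size
  s <- ctrw_scaling(simulation_config(ctrw_alpha = 0.5, seed = 31),
                    n_walkers = 2e4)
  expect_lt(abs(s$slope - 0.5), 0.05)
  # near-classical surrogate: finite-mean waits, slope about 1
  m <- anomdiff:::ctrw_ensemble_msd(1.9, 0.02, 0.45, 5000,
                                    exp(seq(log(10), log(100),
                                            length.out = 8)), seed = 7)
  tg <- as.numeric(names(m))
  slope <- unname(coef(lm(log(m) ~ log(tg)))[2])
  expect_equal(slope, 1, tolerance = 0.1)
})

test_that("simulation config is validated", {
  expect_error(simulation_config(ctrw_alpha = 2.2), "0, 2")
  expect_error(simulation_config(waiting_scale = 0))
  expect_error(simulation_config(slot_edges = c(1, 1, 2)), "increasing")
})
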