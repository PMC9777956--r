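# Frozen reference values were computed before implementation with an
# independent high-precision route (50-digit arithmetic): direct summation
# of the similarity series and fixed-Talbot inversion of the Laplace-domain
# propagator, which agree with each other to ~1e-30.

test_that("similarity series reproduces frozen high-precision values", {
  # Gaussian reduction f = t^(-1/2) pi^(-1/2) exp(-g^2/(4t)) at gamma = 1/2
  expect_equal(as.numeric(series_f(1, 0, -0.5, 0.5)), 1 / sqrt(pi),
               tolerance = 1e-12)
  expect_equal(as.numeric(series_f(1, 1, -0.5, 0.5)),
               exp(-0.25) / sqrt(pi), tolerance = 1e-12)
  # strongly subdiffusive case, alpha = 0.47
  expect_equal(as.numeric(series_f(1, 1, -0.765, 0.235)),
               0.38147860372060624, tolerance = 1e-10)
})

test_that("reciprocal Gamma vanishes exactly at the poles", {
  expect_identical(recip_gamma(c(0, -1, -2, -7)), c(0, 0, 0, 0))
  expect_equal(recip_gamma(0.5), 1 / gamma(0.5), tolerance = 1e-14)
  expect_equal(recip_gamma(-1.5), 1 / gamma(-1.5), tolerance = 1e-12)
  # at alpha = 1 all odd-k series terms carry Gamma at a pole:
  # -k*gamma - beta = (1 - k)/2 is a non-positive integer for odd k
  k <- seq(1, 21, by = 2)
  expect_identical(recip_gamma((1 - k) / 2), rep(0, length(k)))
})

test_that("propagator reduces to the Gaussian kernel at alpha = 1", {
  p <- fractional_params(1, 1)
  expect_equal(as.numeric(evaluate_propagator(0, 1, p)), 1 / sqrt(4 * pi),
               tolerance = 1e-9)
  for (t in c(0.1, 1, 5)) {
    x <- seq(-5, 5, length.out = 41) * sqrt(2 * t)
    got <- as.numeric(evaluate_propagator(x, t, p))
    ref <- gaussian_limit_propagator(x, t, 1)
    expect_lt(max(abs(got - ref) / ref), 1e-6)
  }
})

test_that("gaussian limit closed form and its normalization", {
  expect_equal(gaussian_limit_propagator(0, 1, 1), 0.28209479177387814)
  expect_equal(gaussian_limit_propagator(2, 1, 1),
               0.28209479177387814 * exp(-1), tolerance = 1e-12)
  q <- integrate(gaussian_limit_propagator, -Inf, Inf, t = 0.3, k = 2)
  expect_equal(q$value, 1, tolerance = 1e-9)
})

test_that("Talbot inversion matches the frozen fixture and the Gaussian", {
  p <- fractional_params(0.5, 1)
  expect_equal(laplace_oracle(1, 1, p), 0.19166770828534177,
               tolerance = 1e-8)
  expect_equal(as.numeric(evaluate_propagator(1, 1, p)),
               0.19166770828534177, tolerance = 1e-8)
  p1 <- fractional_params(1, 1)
  expect_equal(laplace_oracle(0, 1, p1), 1 / sqrt(4 * pi),
               tolerance = 1e-8)
  # symmetry in the sign of x - x0
  d <- c(0.3, 1.1, 2.7)
  expect_equal(laplace_oracle(5 + d, 2, p, x0 = 5),
               laplace_oracle(5 - d, 2, p, x0 = 5), tolerance = 1e-12)
})

test_that("series and Talbot routes agree in the series regime", {
  for (alpha in c(0.47, 0.8, 1.2, 1.5)) {
    p <- fractional_params(alpha, 1)
    for (t in c(0.5, 2)) {
      x <- c(0, 0.5, 1, 2, 3) * t^(alpha / 2)   # g/t^gamma up to 3
      a <- as.numeric(evaluate_propagator(x, t, p))
      b <- laplace_oracle(x, t, p)
      expect_lt(max(abs(a - b) / abs(b)), 1e-6)
    }
  }
})

test_that("propagator is symmetric and normalized", {
  for (alpha in c(0.47, 1, 1.5)) {
    p <- fractional_params(alpha, 0.7)
    d <- c(0.25, 1, 3, 8)
    expect_equal(as.numeric(evaluate_propagator(50 + d, 1.5, p, x0 = 50)),
                 as.numeric(evaluate_propagator(50 - d, 1.5, p, x0 = 50)),
                 tolerance = 1e-12)
    for (t in c(0.5, 5)) {
      half <- 40 * sqrt(msd(p, t))
      q <- integrate(function(u) evaluate_propagator(u, t, p, x0 = 50),
                     50 - half, 50 + half, rel.tol = 1e-7,
                     subdivisions = 500L)
      expect_lt(abs(q$value - 1), 1e-3)
    }
  }
})

test_that("fallback regime is flagged and can be forbidden", {
  p <- fractional_params(0.8, 1)
  v <- evaluate_propagator(c(0, 1, 30), 1, p)   # g = 30 is beyond the series
  expect_identical(attr(v, "fallback"), c(FALSE, FALSE, TRUE))
  strict <- series_settings(allow_fallback = FALSE)
  expect_error(evaluate_propagator(30, 1, p, settings = strict), "fallback")
  # non-convergence at k_max without fallback is a diagnostic error
  tight <- series_settings(k_max = 3L, term_tol = 1e-30,
                           allow_fallback = FALSE)
  err <- tryCatch(series_f(1, 2, -0.765, 0.235, tight), error = identity)
  expect_s3_class(err, "anomdiff_series_error")
  expect_true(is.finite(err$partial_sum))
})

test_that("mean squared displacement follows the fractional power law", {
  expect_equal(msd(fractional_params(1, 1), 2), 4)
  for (alpha in c(0.47, 0.9, 1.6)) {
    p <- fractional_params(alpha, 3)
    t <- c(0.3, 1, 4)
    expect_equal(msd(p, 2 * t) / msd(p, t), rep(2^alpha, 3))
  }
  # quadrature of x^2 P(x) matches the closed form within 1%
  p <- fractional_params(0.47, 1)
  q <- integrate(function(u) u^2 * evaluate_propagator(u, 1, p), -60, 60,
                 rel.tol = 1e-7, subdivisions = 500L)
  expect_equal(q$value, 2 / gamma(1.47), tolerance = 0.01)
  expect_equal(msd(p, 1), 2 / gamma(1.47), tolerance = 1e-12)
  # log-log slope of the msd law recovers alpha
  t <- exp(seq(log(0.1), log(10), length.out = 20))
  slope <- unname(coef(lm(log(msd(p, t)) ~ log(t)))[2])
  expect_equal(slope, 0.47, tolerance = 0.01)
})

test_that("admissibility verdicts and rejections", {
  rep1 <- check_admissibility(fractional_params(1, 1),
                              x_grid = seq(-10, 10, length.out = 41),
                              t_grid = c(0.5, 1, 5))
  expect_true(rep1$admissible)
  expect_true(rep1$nonneg_ok)
  expect_true(rep1$normalized_ok)
  # slot masses of a normalized density never exceed 1
  rep2 <- check_admissibility(fractional_params(0.47, 1),
                              x_grid = seq(40, 60, length.out = 21),
                              t_grid = 1, x0 = 50,
                              slot_edges = tfc_edges())
  expect_true(rep2$slot_mass_ok)
  # alpha outside (0,2) cannot even be constructed
  expect_error(check_admissibility(fractional_params(2.5, 1), 0:1, 1))
})

test_that("series settings are validated", {
  expect_error(series_settings(k_max = 0), "k_max")
  expect_error(series_settings(term_tol = 0))
  expect_error(series_settings(regime_threshold = -1))
  expect_error(series_f(0, 1, -0.5, 0.5), "positive")
  expect_error(series_f(1, -1, -0.5, 0.5), "nonnegative")
  expect_error(series_f(1, 1, -0.4, 0.5), "gamma")
})
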