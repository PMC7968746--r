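# Gamma path densities, mixture construction, binning probabilities, sampling.

test_that("path density matches the exponential special case and normalizes", {
  expect_equal(path_density(1, tau = 1, L = 1), exp(-1), tolerance = 1e-12)
  # Erlang mode at (L - 1) * tau
  grid <- seq(0.01, 30, by = 0.01)
  expect_equal(grid[which.max(path_density(grid, tau = 2, L = 4))], 6,
               tolerance = 1e-2)
  # real (non-integer) L normalizes too
  q <- integrate(path_density, 0, 200, tau = 2, L = 3.5)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(path_density(1, tau = -1, L = 2), "tau")
  expect_error(path_density(1, tau = 1, L = 0), "L")
  expect_error(path_density(-0.5, tau = 1, L = 1), "t")
})

test_that("path CDF agrees with quadrature of the density", {
  expect_equal(path_cdf(0, tau = 3, L = 2.2), 0)
  expect_equal(path_cdf(5 * log(2), tau = 5, L = 1), 0.5, tolerance = 1e-12)
  oracle <- integrate(path_density, 0, 5, tau = 1, L = 3)$value
  expect_equal(path_cdf(5, tau = 1, L = 3), oracle, tolerance = 1e-8)
  # monotone, limits to 1
  t <- seq(0, 100, by = 0.5)
  expect_true(all(diff(path_cdf(t, tau = 2, L = 4)) >= 0))
  expect_equal(path_cdf(1e4, tau = 2, L = 4), 1, tolerance = 1e-12)
})

test_that("mixture weights follow the relative-flux parameterization", {
  expect_equal(mixture_weights(numeric(0)), 1)
  expect_equal(mixture_weights(c(1, 1)), rep(1 / 3, 3))
  expect_equal(mixture_weights(3), c(0.25, 0.75))
  expect_error(mixture_weights(-0.1), "x")
  for (k in 1:5) {
    x <- withr::with_seed(k, runif(k, 0, 10))
    expect_equal(sum(mixture_weights(x)), 1, tolerance = 1e-12)
  }
})

test_that("mixture density is a normalized convex combination and is nested", {
  m1 <- fp_model(tau = 2, L = 3)
  t <- seq(0, 50, by = 0.25)
  expect_equal(mixture_density(t, m1), path_density(t, 2, 3), tolerance = 1e-14)
  # a zero-flux extra path changes nothing, pointwise
  m2 <- fp_model(tau = c(2, 7), L = c(3, 11), x = 0)
  expect_lt(max(abs(mixture_density(t, m2) - mixture_density(t, m1))), 1e-12)
  # normalization over a wide window
  m <- two_path_model()
  horizon <- 50 * max(m$tau * m$L)
  q <- integrate(function(u) mixture_density(u, m), 0, horizon,
                 rel.tol = 1e-9, subdivisions = 500L)
  expect_gte(q$value, 0.999)
})

test_that("sampled moments match the analytic mixture moments", {
  # equal-weight mixture with path means 10 and 50 ms: overall mean 30 ms
  m <- fp_model(tau = c(10 / 3, 50 / 8), L = c(3, 8), x = 1)
  n <- 1e5
  s <- sample_fp_times(m, n, seed = 11)
  p <- mixture_weights(m$x)
  Tm <- m$tau * m$L
  mu <- sum(p * Tm)                         # 30
  v_paths <- m$L * m$tau^2
  v_tot <- sum(p * (v_paths + Tm^2)) - mu^2 # law of total variance
  expect_equal(mu, 30)
  expect_lt(abs(mean(s) - mu), 3 * sqrt(v_tot / n))
  expect_lt(abs(var(s) - v_tot), 4 * v_tot * sqrt(2 / n))
  # determinism contract
  expect_identical(s, sample_fp_times(m, n, seed = 11))
  # empirical CV of a single L = 4 path: 1/sqrt(4)
  s4 <- sample_fp_times(fp_model(tau = 2, L = 4), 1e5, seed = 3)
  expect_lt(abs(sd(s4) / mean(s4) - 0.5), 0.01)
})

test_that("path-choice frequencies match the mixture weights", {
  m <- fp_model(tau = c(1, 100), L = c(2, 2), x = 0.5)  # p = (2/3, 1/3)
  s <- sample_fp_times(m, 1e5, seed = 5)
  # exact probability of exceeding 20 ms under the mixture
  expected <- 1 - mixture_cdf(20, m)
  frac_slow <- mean(s > 20)
  expect_lt(abs(frac_slow - expected),
            3 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("bin probabilities telescope and match closed forms", {
  m <- two_path_model()
  edges <- seq(0, 120, by = 0.5)
  pr <- bin_probability(edges[-length(edges)], edges[-1], m)
  expect_equal(sum(pr), mixture_cdf(120, m), tolerance = 1e-10)
  # exponential closed form
  e1 <- fp_model(tau = 4, L = 1)
  expect_equal(bin_probability(2, 3, e1), exp(-2 / 4) - exp(-3 / 4),
               tolerance = 1e-12)
  expect_error(bin_probability(3, 2, m), "lo < hi")
  # midpoint approximation converges at second order away from t = 0
  center <- 20
  err <- vapply(c(0.4, 0.2, 0.1), function(dt) {
    abs(bin_probability(center - dt / 2, center + dt / 2, m, "midpoint") -
          bin_probability(center - dt / 2, center + dt / 2, m, "exact")) / dt
  }, numeric(1))
  expect_lt(err[2] / err[1], 0.35)  # halving dt cuts the density error ~4x
  expect_lt(err[3] / err[2], 0.35)
})

test_that("path summaries and their inverse round-trip the model", {
  m8 <- fp_model(tau = 2, L = 8)
  s <- path_summaries(m8)
  expect_equal(s$mean_completion, 16)
  expect_equal(s$cv, 1 / sqrt(8), tolerance = 1e-6)
  expect_equal(s$weight, 1)

  m <- fp_model(tau = c(2.5, 3.2, 1), L = c(4, 25, 2), x = c(2 / 3, 0.2))
  s <- path_summaries(m)
  expect_equal(sum(s$weight), 1, tolerance = 1e-12)
  back <- fp_model_from_summaries(s)
  expect_equal(back$tau, m$tau, tolerance = 1e-10)
  expect_equal(back$L, m$L, tolerance = 1e-10)
  expect_equal(back$x, m$x, tolerance = 1e-10)
})

test_that("model construction rejects invalid parameters", {
  expect_error(fp_model(tau = c(1, 2), L = 1), "equal")
  expect_error(fp_model(tau = 1, L = 1, x = 0.5), "length")
  expect_error(fp_model(tau = c(1, 2), L = c(1, 1), x = -1), "x")
})
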