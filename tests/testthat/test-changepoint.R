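# Negative-binomial pmf, the changepoint joint density, the exact
# quadrature oracle, and the MCMC sampler.

test_that("nb_log_pmf matches the closed form and the log-gamma oracle", {
  expect_equal(nb_log_pmf(0, mu = 1, phi = 1), log(0.5), tolerance = 1e-12)
  # (phi/(mu+phi))^phi at y = 0
  expect_equal(nb_log_pmf(0, mu = 3, phi = 2), 2 * log(2 / 5),
               tolerance = 1e-12)
  expect_equal(nb_log_pmf(3, mu = 2, phi = 4), nb_lpmf_oracle(3, 2, 4),
               tolerance = 1e-10)
  set.seed(21)
  for (i in 1:20) {
    y <- sample(0:50, 1); mu <- runif(1, 0.1, 30); phi <- runif(1, 0.1, 10)
    expect_equal(nb_log_pmf(y, mu, phi), nb_lpmf_oracle(y, mu, phi),
                 tolerance = 1e-10)
  }
  expect_error(nb_log_pmf(1, mu = -1, phi = 1), "mu")
  expect_error(nb_log_pmf(1, mu = 1, phi = 0), "phi")
  expect_error(nb_log_pmf(1.5, mu = 1, phi = 1), "integer")
})

test_that("nb_log_pmf normalizes over its support", {
  for (pars in list(c(5, 2), c(1, 1), c(20, 0.5), c(0.3, 4), c(10, 10))) {
    expect_equal(sum(nb_log_pmf(0:10000, pars[1], pars[2], log = FALSE)), 1,
                 tolerance = 1e-8)
  }
})

test_that("log_joint unrolls to pmf terms plus priors", {
  priors <- changepoint_priors(mu_prior_mean = 10, phi_prior_mean = 1)
  s <- monthly_counts(c(3, 7), "2000-01")
  # hand-composed: early pmf for month 1, late pmf for month 2, exponential
  # log priors, and log of the uniform prior over the single candidate
  params <- c(2, 8, 1, 1)
  by_hand <- nb_lpmf_oracle(3, 2, 1) + nb_lpmf_oracle(7, 8, 1) +
    dexp(2, 1 / 10, log = TRUE) + dexp(8, 1 / 10, log = TRUE) +
    dexp(1, 1, log = TRUE) + dexp(1, 1, log = TRUE) + log(1)
  expect_equal(log_joint(s, 2, params, priors), by_hand, tolerance = 1e-10)

  # likelihood symmetry: early/late swap on the reversed series
  s4 <- monthly_counts(c(0, 2, 5, 9), "2000-01")
  expect_equal(log_joint(s4, 3, c(1, 6, 2, 3)),
               log_joint(reverse_series(s4), 3, c(6, 1, 3, 2)),
               tolerance = 1e-10)
  expect_error(log_joint(s4, 1, c(1, 1, 1, 1)), "tau")
  expect_error(log_joint(s4, 5, c(1, 1, 1, 1)), "tau")
})

test_that("the exact posterior is a distribution and localizes a hard jump", {
  s <- monthly_counts(c(rep(0, 5), rep(10, 5)), "2000-01")
  post <- exact_changepoint_posterior(s)
  expect_equal(sum(post$tau_probs), 1, tolerance = 1e-8)
  expect_true(all(post$tau_probs >= 0))
  # argmax at the first late month (index 6 -> 2000-06)
  expect_equal(post$map_index, 6L)
  expect_equal(post$map_month, "2000-06")
  # argmax stable under grid refinement
  finer <- exact_changepoint_posterior(s, grid = list(n_mu = 96, n_phi = 96))
  expect_equal(finer$map_index, post$map_index)
  expect_lt(tv_dist(finer$tau_probs, post$tau_probs), 0.01)
})

test_that("the oracle is exactly time-reversal symmetric", {
  set.seed(31)
  for (i in 1:4) {
    s <- monthly_counts(rnbinom(20, size = 1, mu = 4), "1990-01")
    a <- exact_changepoint_posterior(s)$tau_probs
    b <- exact_changepoint_posterior(reverse_series(s))$tau_probs
    expect_equal(unname(a), unname(rev(b)), tolerance = 1e-8)
  }
})

test_that("the oracle refuses series beyond its scale", {
  s <- monthly_counts(rep(1, 121), "1970-01")
  expect_error(exact_changepoint_posterior(s), "at most 120")
})

test_that("the sampler is seeded-reproducible and agrees with the oracle", {
  cfg <- sim_series_config(n_months = 40, changepoint_month = 20,
                           mu_early = 2, mu_late = 12, seed = 17)
  s <- simulate_count_series(cfg)
  sc <- sampler_config(iterations = 1200, chains = 2, seed = 5)
  fit1 <- sample_changepoint_posterior(s, config = sc)
  fit2 <- sample_changepoint_posterior(s, config = sc)
  expect_identical(fit1$tau_probs, fit2$tau_probs)
  expect_identical(fit1$draws, fit2$draws)

  expect_equal(sum(fit1$tau_probs), 1, tolerance = 1e-8)
  ex <- exact_changepoint_posterior(s)
  expect_lt(tv_dist(fit1$tau_probs, ex$tau_probs), 0.05)
  expect_true(all(fit1$draws > 0))
  expect_equal(dimnames(fit1$draws)[[3]],
               c("mu_early", "mu_late", "phi_early", "phi_late"))
})

test_that("sampler reversal symmetry holds within sampling error", {
  cfg <- sim_series_config(n_months = 30, changepoint_month = 12,
                           mu_early = 3, mu_late = 15, seed = 8)
  s <- simulate_count_series(cfg)
  sc <- sampler_config(iterations = 1500, chains = 2, seed = 4)
  f <- sample_changepoint_posterior(s, config = sc)
  r <- sample_changepoint_posterior(reverse_series(s), config = sc)
  expect_lt(tv_dist(f$tau_probs, rev(r$tau_probs)), 0.05)
})

test_that("posterior evidence near the true changepoint grows with jump size", {
  # oracle-based: median mass within +/-6 months of the planted jump is
  # non-decreasing in the late/early rate ratio
  ratios <- c(1, 2, 4, 8)
  med_mass <- vapply(ratios, function(rho) {
    mass <- vapply(1:8, function(r) {
      cfg <- sim_series_config(n_months = 40, changepoint_month = 20,
                               mu_early = 2, mu_late = 2 * rho,
                               seed = 500 + r)
      post <- exact_changepoint_posterior(simulate_count_series(cfg),
                                          grid = list(n_mu = 32, n_phi = 32))
      idx <- cp_candidates(40)
      sum(post$tau_probs[abs(idx - 20) <= 6])
    }, numeric(1))
    median(mass)
  }, numeric(1))
  expect_true(all(diff(med_mass) >= -0.02))
  expect_gt(med_mass[4], med_mass[1])
})

test_that("flat prior-predictive series yield a near-uniform average posterior", {
  set.seed(600)
  n <- 16
  n_sims <- 40
  probs <- matrix(NA_real_, n_sims, n - 1)
  for (r in 1:n_sims) {
    mu <- rexp(1, 1 / 10); phi <- rexp(1, 1)
    y <- rnbinom(n, size = phi, mu = mu)
    s <- monthly_counts(y, "2000-01")
    probs[r, ] <- exact_changepoint_posterior(
      s, grid = list(n_mu = 32, n_phi = 32))$tau_probs
  }
  avg <- colMeans(probs)
  se <- apply(probs, 2, function(x) sd(x) / sqrt(n_sims))
  expect_true(all(abs(avg - 1 / (n - 1)) < 4 * se + 1e-3))
})

test_that("segmentation recovers two planted jumps and respects its guards", {
  set.seed(44)
  counts <- c(rnbinom(49, size = 2, mu = 2), rnbinom(50, size = 2, mu = 10),
              rnbinom(51, size = 2, mu = 3))
  s <- monthly_counts(counts, "1980-01")
  sc <- sampler_config(iterations = 800, chains = 2, seed = 10)
  fits <- segment_changepoints(s, config = sc, max_segments = 3,
                               min_segment_length = 24)
  expect_gte(length(fits), 2)
  maps <- vapply(fits, function(f) ym_diff(f$map_month, "1980-01") + 1L,
                 integer(1))
  expect_true(any(abs(maps - 50) <= 5))
  expect_true(any(abs(maps - 100) <= 5))

  # max_segments = 1: a single fit on the full series
  one <- segment_changepoints(s, config = sc, max_segments = 1,
                              min_segment_length = 24)
  expect_length(one, 1)
  expect_equal(one[[1]]$n_months, length(counts))

  # short series: no recursion
  short <- monthly_counts(counts[1:30], "1980-01")
  fits_short <- segment_changepoints(short, config = sc, max_segments = 3,
                                     min_segment_length = 24)
  expect_length(fits_short, 1)
})
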