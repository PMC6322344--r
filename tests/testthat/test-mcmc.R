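test_that("log-likelihood matches hand values and never overflows", {
  d1 <- intercept_design(1, 1)
  expect_equal(log_likelihood(0, d1), log(0.5))
  d <- encode_design(generate_cohort(generator_config(n = 37, seed = 2)))
  expect_equal(log_likelihood(rep(0, 8), d), 37 * log(0.5))
  # softplus asymptotics: eta = 50, y = 1 -> about -exp(-50), finite
  expect_equal(log_likelihood(50, d1), -exp(-50))
  expect_true(is.finite(log_likelihood(500, d1)))
  expect_true(is.finite(log_likelihood(-500, d1)))
  expect_error(log_likelihood(NaN, d1), "non-finite")
})

test_that("log-prior matches the closed normal density and brute force", {
  pr <- prior_spec(0, 1000)
  mode_val <- 8 * (-0.5 * log(2 * pi * 1000))
  expect_equal(log_prior(rep(0, 8), pr), mode_val)
  # one slot, one SD from the mean: mode value - 0.5
  pr1 <- prior_spec(2, 9)
  expect_equal(log_prior(2 + 3, pr1),
               -0.5 * log(2 * pi * 9) - 0.5)
  # brute-force density-product oracle on random inputs
  set.seed(4)
  for (i in 1:5) {
    beta <- rnorm(8, sd = 5)
    mu <- rnorm(8); v <- rexp(8) + 0.1
    manual <- sum(log(1 / sqrt(2 * pi * v) * exp(-(beta - mu)^2 / (2 * v))))
    expect_equal(log_prior(beta, prior_spec(mu, v)), manual, tolerance = 1e-10)
  }
  expect_error(prior_spec(0, 0), "strictly positive")
})

test_that("log-posterior is likelihood plus prior and has the right limits", {
  d <- encode_design(generate_cohort(generator_config(n = 60, seed = 6)))
  pr <- prior_spec(0, 1000)
  set.seed(5)
  beta <- rnorm(8)
  expect_identical(log_posterior(beta, d, pr),
                   log_likelihood(beta, d) + log_prior(beta, pr))
  # 1-parameter problem: flat-prior argmax approaches the MLE,
  # point-mass prior argmax approaches the prior mean
  d1 <- intercept_design(37, 61)
  grid <- seq(-2, 2, by = 1e-3)
  mle <- unname(fit_logistic(d1)$coefficients)
  post_flat <- vapply(grid, function(b) log_posterior(b, d1, prior_spec(0, 1e8)), 1)
  expect_equal(grid[which.max(post_flat)], mle, tolerance = 2e-3)
  post_tight <- vapply(grid, function(b) log_posterior(b, d1, prior_spec(1, 1e-6)), 1)
  expect_equal(grid[which.max(post_tight)], 1, tolerance = 2e-3)
})

test_that("chains are reproducible and respect their configuration", {
  d <- encode_design(generate_cohort(generator_config(n = 400, seed = 9)))
  cfg <- chain_config(n_chains = 2, iterations = 500, burnin = 200, thin = 5,
                      seed = 77, inner_updates = 2)
  s1 <- run_chains(d, prior_spec(), cfg)
  s2 <- run_chains(d, prior_spec(), cfg)
  expect_identical(s1$draws, s2$draws)
  expect_equal(dim(s1$draws), c(100, 8, 2))
  expect_true(all(s1$accept > 0 & s1$accept < 1))
  expect_error(chain_config(iterations = 501, thin = 5), "multiple")
  expect_error(chain_config(n_chains = 1), "n_chains")
})

test_that("intercept-only posterior agrees with the closed-form MLE", {
  d <- intercept_design(5229, 6007)
  cfg <- chain_config(n_chains = 2, iterations = 2500, burnin = 500, thin = 5,
                      seed = 123, inner_updates = 1)
  s <- run_chains(d, prior_spec(0, 1000), cfg)
  post <- summarize_posterior(s)
  mle <- log(5229 / 778)
  mle_se <- sqrt(1 / 5229 + 1 / 778)
  expect_lt(abs(post$mean - mle), 3 * post$mc_error)
  expect_lt(abs(post$sd / mle_se - 1), 0.10)
})

test_that("posterior summaries are correct on constructed samples", {
  # constant draws: degenerate summary
  cfg <- chain_config(n_chains = 2, iterations = 500, burnin = 0, thin = 1, seed = 1)
  const <- structure(list(
    draws = array(7, c(100, 1, 2), dimnames = list(NULL, "b0", NULL)),
    accept = matrix(0.4, 1, 2), config = cfg, slots = "b0"),
    class = "posterior_samples")
  ps <- summarize_posterior(const)
  expect_equal(ps$mean, 7)
  expect_equal(ps$median, 7)
  expect_equal(ps$sd, 0)
  expect_equal(c(ps$hpd_lower, ps$hpd_upper), c(7, 7))

  small <- const
  small$draws <- const$draws[1:20, , , drop = FALSE]
  expect_error(summarize_posterior(small), "100 pooled draws")
})

test_that("the HPD interval matches an exhaustive shortest-window search", {
  set.seed(10)
  for (i in 1:10) {
    x <- switch(1 + i %% 3, rnorm(251), rexp(300), rbeta(173, 2, 5))
    got <- hpd_interval(x, 0.9)
    # independent oracle: check every window of ceiling(0.9 n) sorted draws
    xs <- sort(x); n <- length(xs); k <- ceiling(0.9 * n)
    best <- c(Inf, NA, NA)
    for (j in 1:(n - k + 1)) {
      w <- xs[j + k - 1] - xs[j]
      if (w < best[1]) best <- c(w, xs[j], xs[j + k - 1])
    }
    expect_equal(got, best[2:3])
  }
})

test_that("HPD intervals are never longer than equal-tail intervals", {
  set.seed(20)
  for (i in 1:20) {
    x <- rgamma(500, shape = sample(1:5, 1))
    hpd <- hpd_interval(x, 0.95)
    et <- unname(quantile(x, c(0.025, 0.975), type = 1))
    expect_lte(hpd[2] - hpd[1], et[2] - et[1] + 1e-12)
  }
})

test_that("batch-means MC error is calibrated on iid draws", {
  set.seed(30)
  x <- rnorm(1e4)
  expect_lt(abs(mc_error_batch(x) - 0.01), 0.005)  # within 50% of sd/sqrt(N)
})
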