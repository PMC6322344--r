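test_that("intercept-only fits recover their closed forms", {
  d <- intercept_design(5229, 6007)
  lg <- fit_logistic(d)
  expect_true(lg$converged)
  expect_equal(unname(lg$coefficients), log(5229 / 778), tolerance = 1e-8)
  expect_equal(unname(lg$se), sqrt(1 / 5229 + 1 / 778), tolerance = 1e-6)

  lb <- fit_log_binomial(d)
  expect_true(lb$converged)
  expect_equal(unname(lb$coefficients), log(5229 / 6007), tolerance = 1e-8)

  po <- fit_robust_poisson(d)
  expect_true(po$converged)
  expect_equal(unname(po$coefficients), log(5229 / 6007), tolerance = 1e-8)
  # hand-derived intercept-only sandwich: sqrt((1 - p) / (n p))
  p <- 5229 / 6007
  expect_equal(unname(po$se), sqrt((1 - p) / (6007 * p)), tolerance = 1e-6)

  bal <- fit_logistic(intercept_design(50, 100))
  expect_equal(unname(bal$coefficients), 0, tolerance = 1e-8)
})

test_that("saturated one-covariate fits match the crude 2x2 measures", {
  d <- gender_design(327, 2501, 451, 2728)
  or <- crude_odds_ratio(327, 2501, 451, 2728)
  rr <- crude_risk_ratio(327, 2501, 451, 2728)
  expect_equal(unname(fit_logistic(d)$coefficients[2]), log(or), tolerance = 1e-6)
  lb <- fit_log_binomial(d)
  expect_equal(unname(lb$coefficients[2]), log(rr), tolerance = 1e-6)
  po <- fit_robust_poisson(d)
  expect_equal(unname(po$coefficients[2]), log(rr), tolerance = 1e-6)
  # same point estimates; on a saturated design the sandwich collapses to
  # the binomial variance, so the SEs coincide there too
  expect_equal(unname(po$coefficients), unname(lb$coefficients), tolerance = 1e-6)
  expect_equal(unname(po$se), unname(lb$se), tolerance = 1e-6)
})

test_that("sandwich and binomial standard errors differ off the saturated case", {
  coh <- generate_cohort(generator_config(n = 1200, seed = 55))
  d <- encode_design(coh)
  po <- fit_robust_poisson(d)
  # naive (model-based) Poisson SEs from the information alone
  mu <- exp(drop(d$X %*% po$coefficients))
  naive <- sqrt(diag(solve(crossprod(d$X, d$X * mu))))
  expect_false(isTRUE(all.equal(unname(po$se), unname(naive), tolerance = 1e-2)))
  # sandwich correction shrinks the naive Poisson SEs for a common outcome
  expect_true(all(po$se < naive))
})

test_that("log-binomial boundary cases are flagged, never silently wrong", {
  all_ones <- intercept_design(40, 40)
  lb <- fit_log_binomial(all_ones)
  expect_false(lb$converged)
  expect_true(lb$boundary)
  expect_match(lb$message, "boundary")
})

test_that("rank-deficient designs and separation are rejected", {
  X <- cbind(`(Intercept)` = 1, a = c(0, 1, 0, 1), b = c(0, 1, 0, 1))
  expect_error(fit_logistic(new_design(X, c(0, 1, 1, 0))), "rank deficient")
  # perfectly separated covariate
  Xs <- cbind(`(Intercept)` = 1, x = c(0, 0, 0, 1, 1, 1))
  expect_error(fit_logistic(new_design(Xs, c(0, 0, 0, 1, 1, 1))), "separation")
})

test_that("the score vanishes at the optimum for all three fitters", {
  coh <- generate_cohort(generator_config(n = 1500, seed = 42))
  d <- encode_design(coh)
  tol <- 1e-8

  lg <- fit_logistic(d, tol = tol)
  p <- plogis(drop(d$X %*% lg$coefficients))
  expect_lt(max(abs(crossprod(d$X, d$y - p))), tol)

  po <- fit_robust_poisson(d, tol = tol)
  mu <- exp(drop(d$X %*% po$coefficients))
  expect_lt(max(abs(crossprod(d$X, d$y - mu))), tol)

  lb <- fit_log_binomial(d, tol = tol)
  if (lb$converged) {
    pb <- exp(drop(d$X %*% lb$coefficients))
    expect_lt(max(abs(crossprod(d$X, (d$y - pb) / (1 - pb)))), tol)
  } else {
    expect_true(lb$boundary)
  }
})

test_that("Newton-Raphson matches a grid-search maximizer on a 1-parameter problem", {
  d <- intercept_design(37, 61)
  fit <- fit_logistic(d, tol = 1e-10)
  grid <- seq(-2, 2, by = 1e-5)
  ll <- vapply(grid, function(b) sum(d$y * b - log1p(exp(b))), 1)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)], tolerance = 2e-5)
})

test_that("fits agree with glm() and sandwich::vcovHC as independent cross-checks", {
  skip_if_not_installed("sandwich")
  coh <- generate_cohort(generator_config(n = 2000, seed = 8))
  df <- as.data.frame(coh)
  X <- encode_design(coh)$X
  d <- encode_design(coh)

  ref_lg <- glm(d$y ~ X - 1, family = binomial())
  lg <- fit_logistic(d)
  expect_equal(unname(lg$coefficients), unname(coef(ref_lg)), tolerance = 1e-6)
  expect_equal(unname(lg$se), unname(sqrt(diag(vcov(ref_lg)))), tolerance = 1e-5)

  ref_po <- glm(d$y ~ X - 1, family = poisson())
  po <- fit_robust_poisson(d)
  expect_equal(unname(po$coefficients), unname(coef(ref_po)), tolerance = 1e-6)
  hc0 <- sqrt(diag(sandwich::vcovHC(ref_po, type = "HC0")))
  expect_equal(unname(po$se), unname(hc0), tolerance = 1e-5)
})

test_that("Wald summaries transform estimates and SEs correctly", {
  d <- intercept_design(30, 60)
  fit <- fit_logistic(d)
  fit$coefficients[] <- 0; fit$se[] <- 1
  w <- wald_summary(fit, 0.95)
  expect_equal(unname(w$ci[1, ]), c(-1, 1) * qnorm(0.975), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(w$p), 1)
  fit$coefficients[] <- qnorm(0.975)
  w2 <- wald_summary(fit, 0.95)
  expect_equal(unname(w2$p), 0.05, tolerance = 1e-9)
  # published multivariable Male row: estimate -0.2037, SE 0.0786
  fit$coefficients[] <- -0.2037; fit$se[] <- 0.0786
  w3 <- wald_summary(fit, 0.95)
  expect_equal(unname(w3$ci[1, ]), c(-0.358, -0.050), tolerance = 0.002,
               ignore_attr = TRUE)
  expect_error(wald_summary(fit, 1.2), "level")
  # effect measure is exp(estimate) to full precision
  expect_equal(unname(w3$effect), exp(-0.2037))
})
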