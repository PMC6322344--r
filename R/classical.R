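# From-first-principles maximum-likelihood fitters for the three classical
# binary-outcome regressions. All three share a damped Newton/Fisher-scoring
# loop: convergence is declared on the score (max |gradient| < tol), steps
# are halved (max 20 times) whenever a proposal leaves the feasible region or
# decreases the log-likelihood. SEs come from the inverse information at the
# optimum; the robust-Poisson fit replaces them with the HC0 sandwich.

# Numerically stable log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

check_full_rank <- function(X) {
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; drop aliased columns", call. = FALSE)
  }
}

new_fit <- function(model, effect_name, beta, vcov, converged, boundary,
                    iterations, loglik, n, message = NULL) {
  se <- sqrt(pmax(diag(vcov), 0))
  fit <- structure(
    list(model = model, effect_name = effect_name,
         coefficients = beta, se = stats::setNames(se, names(beta)),
         vcov = vcov, converged = converged, boundary = boundary,
         iterations = iterations, loglik = loglik, n = n,
         message = message),
    class = "caries_fit")
  wald_summary(fit, level = 0.95)
}

#' Wald inference for a classical fit
#'
#' Augments a fit with z statistics, two-sided normal p-values, Wald
#' confidence intervals `estimate +/- z * se` at the requested level, and the
#' effect measure `exp(estimate)` (odds ratio for the logistic model, risk
#' ratio for the log-binomial and Poisson models).
#'
#' @param fit A `caries_fit`.
#' @param level Confidence level in (0, 1).
#' @return The fit with elements `z`, `p`, `ci` (matrix with columns lower,
#'   upper), `effect` and `level` filled in.
#' @export
wald_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "caries_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  est <- fit$coefficients
  z <- est / fit$se
  q <- stats::qnorm((1 + level) / 2)
  ci <- cbind(lower = est - q * fit$se, upper = est + q * fit$se)
  rownames(ci) <- names(est)
  fit$z <- z
  fit$p <- 2 * stats::pnorm(-abs(z))
  fit$ci <- ci
  fit$effect <- exp(est)
  fit$level <- level
  fit
}

# Shared damped Newton loop. `family` supplies, for a linear predictor eta:
#   mu(eta)      fitted mean
#   score_w(...) per-record score weight so that gradient = X' (score_w)
#   info_w(...)  per-record information weight so that info = X' diag(w) X
#   loglik(...)  log-likelihood
#   feasible(eta) whether eta is inside the parameter space
newton_fit <- function(design, family, beta0, tol, max_iter, sep_threshold = 30) {
  X <- design$X; y <- design$y
  check_full_rank(X)
  beta <- beta0
  eta <- drop(X %*% beta)
  ll <- family$loglik(y, eta)
  converged <- FALSE; boundary <- FALSE; msg <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    sw <- family$score_w(y, eta)
    score <- drop(crossprod(X, sw))
    if (max(abs(score)) < tol) { converged <- TRUE; iter <- iter - 1; break }
    w <- family$info_w(y, eta)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { msg <- "singular information matrix"; break }
    # step halving: stay feasible and never decrease the log-likelihood
    accepted <- FALSE
    for (h in 0:20) {
      beta_new <- beta + step / 2^h
      eta_new <- drop(X %*% beta_new)
      if (!family$feasible(eta_new)) next
      ll_new <- family$loglik(y, eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        beta <- beta_new; eta <- eta_new; ll <- ll_new; accepted <- TRUE
        break
      }
    }
    if (!accepted) { boundary <- TRUE; msg <- "step halving exhausted"; break }
    if (max(abs(beta)) > sep_threshold) {
      stop("apparent complete separation: coefficient magnitude exceeded ",
           sep_threshold, call. = FALSE)
    }
  }
  sw <- family$score_w(y, eta)
  score <- drop(crossprod(X, sw))
  if (!converged && max(abs(score)) < tol) converged <- TRUE
  if (!converged && is.null(msg)) msg <- "maximum iterations reached"
  w <- family$info_w(y, eta)
  info <- crossprod(X, X * w)
  list(beta = stats::setNames(beta, colnames(X)), eta = eta, info = info,
       loglik = ll, converged = converged, boundary = boundary,
       iterations = iter, message = msg)
}

#' Logistic regression by Newton-Raphson
#'
#' Maximum-likelihood logistic regression (logit link) of the binary caries
#' outcome on the reference-coded design. Exponentiated coefficients are odds
#' ratios. SEs come from the inverse observed information (for the canonical
#' logit link, observed and expected information coincide).
#'
#' @param design A `caries_design`.
#' @param tol Convergence tolerance on the maximum absolute score component.
#' @param max_iter Maximum Newton iterations.
#' @return A `caries_fit` with 95% Wald intervals.
#' @export
fit_logistic <- function(design, tol = 1e-8, max_iter = 100) {
  fam <- list(
    loglik = function(y, eta) sum(y * eta - softplus(eta)),
    score_w = function(y, eta) y - stats::plogis(eta),
    info_w = function(y, eta) { p <- stats::plogis(eta); p * (1 - p) },
    feasible = function(eta) TRUE
  )
  res <- newton_fit(design, fam, rep(0, ncol(design$X)), tol, max_iter)
  new_fit("logistic", "OR", res$beta, solve(res$info), res$converged,
          res$boundary, res$iterations, res$loglik, length(design$y),
          res$message)
}

#' Log-binomial regression (risk-ratio model)
#'
#' Binomial likelihood with a log link, so exponentiated coefficients are
#' risk ratios. The parameter space is constrained (all fitted probabilities
#' must stay below 1); proposals violating the constraint are step-halved,
#' and when the optimum lies on the boundary the fit is returned with
#' `converged = FALSE` and `boundary = TRUE` rather than a silently wrong
#' answer — non-convergence is a known failure mode of this model. SEs use
#' the expected (Fisher) information, `w = p/(1-p)`.
#'
#' @inheritParams fit_logistic
#' @return A `caries_fit` with 95% Wald intervals.
#' @export
fit_log_binomial <- function(design, tol = 1e-8, max_iter = 100) {
  eps <- 1e-10
  fam <- list(
    loglik = function(y, eta) {
      p <- exp(eta)
      sum(y * eta + (1 - y) * log1p(-pmin(p, 1 - 1e-16)))
    },
    score_w = function(y, eta) { p <- exp(eta); (y - p) / (1 - p) },
    info_w = function(y, eta) { p <- exp(eta); p / (1 - p) },
    feasible = function(eta) all(eta < -eps)
  )
  pbar <- mean(design$y)
  b0 <- c(log(min(pbar, 1 - 1e-6)), rep(0, ncol(design$X) - 1))
  res <- newton_fit(design, fam, b0, tol, max_iter)
  if (!res$converged && max(res$eta) > -1e-6) {
    res$boundary <- TRUE
    res$message <- "MLE on or near the boundary of the parameter space (fitted probability at 1)"
  }
  vcov <- tryCatch(solve(res$info), error = function(e) {
    matrix(NA_real_, ncol(design$X), ncol(design$X))
  })
  new_fit("log-binomial", "RR", res$beta, vcov, res$converged, res$boundary,
          res$iterations, res$loglik, length(design$y), res$message)
}

#' Robust (modified) Poisson regression for binary outcomes
#'
#' Poisson log-link MLE applied to the 0/1 outcome — a standard device for
#' estimating risk ratios when the log-binomial model fails to converge. The
#' Poisson variance is misspecified for binary data, so SEs come from the
#' HC0 sandwich A^-1 B A^-1 with A the model-based information
#' `X' diag(mu) X` and B the outer product of per-record score contributions
#' `X' diag((y - mu)^2) X`.
#'
#' @inheritParams fit_logistic
#' @return A `caries_fit` with sandwich SEs and 95% Wald intervals.
#' @export
fit_robust_poisson <- function(design, tol = 1e-8, max_iter = 100) {
  fam <- list(
    loglik = function(y, eta) sum(y * eta - exp(eta)),
    score_w = function(y, eta) y - exp(eta),
    info_w = function(y, eta) exp(eta),
    feasible = function(eta) all(is.finite(exp(eta)))
  )
  pbar <- mean(design$y)
  if (pbar == 0) stop("all outcomes are zero; log-mean start undefined", call. = FALSE)
  b0 <- c(log(pbar), rep(0, ncol(design$X) - 1))
  res <- newton_fit(design, fam, b0, tol, max_iter)
  mu <- exp(res$eta)
  A <- res$info
  B <- crossprod(design$X, design$X * (design$y - mu)^2)
  Ainv <- solve(A)
  vcov <- Ainv %*% B %*% Ainv
  new_fit("robust-poisson", "RR", res$beta, vcov, res$converged, res$boundary,
          res$iterations, res$loglik, length(design$y), res$message)
}

#' Tidy coefficient table of a classical fit
#'
#' @param fit A `caries_fit`.
#' @return Data frame with one row per coefficient slot: estimate, se, z, p,
#'   Wald interval and the effect measure (exp estimate).
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "caries_fit"))
  data.frame(
    model = fit$model,
    slot = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    z = unname(fit$z),
    p = unname(fit$p),
    lower = unname(fit$ci[, "lower"]),
    upper = unname(fit$ci[, "upper"]),
    effect_measure = unname(fit$effect),
    row.names = NULL
  )
}

#' @export
print.caries_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s%s\n", x$model, x$n,
              if (x$converged) "converged" else "NOT converged",
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  tab <- fit_table(x)
  tab$model <- NULL
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}
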