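# Side-by-side comparison of a classical fit with the Bayesian posterior:
# point estimates, SE vs posterior SD, Wald CI vs HPD interval, and the
# interval lengths. Whether the credible interval is shorter is reported as
# an observed count, never asserted: with a near-flat prior the two
# intervals are near-identical and the direction can flip by Monte-Carlo
# noise.

#' Compare a classical fit with a posterior summary
#'
#' @param fit A converged `caries_fit` (with Wald intervals).
#' @param summary A `posterior_summary` over the same coefficient slots.
#' @return A `comparison_table` data frame, one row per slot, with the MLE
#'   estimate/SE/interval/length alongside the posterior mean/SD/HPD/length,
#'   plus `length_diff` (HPD length - CI length) and `se_diff`
#'   (posterior SD - SE). Attribute `n_hpd_shorter` counts the slots where
#'   the HPD interval is strictly shorter than the Wald interval.
#' @export
compare_fits <- function(fit, summary) {
  stopifnot(inherits(fit, "caries_fit"), inherits(summary, "posterior_summary"))
  if (!identical(names(fit$coefficients), as.character(summary$slot))) {
    stop("coefficient slots of the fit and the posterior summary do not match",
         call. = FALSE)
  }
  ci_len <- unname(fit$ci[, "upper"] - fit$ci[, "lower"])
  hpd_len <- summary$hpd_upper - summary$hpd_lower
  res <- data.frame(
    slot = summary$slot,
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    ci_lower = unname(fit$ci[, "lower"]),
    ci_upper = unname(fit$ci[, "upper"]),
    ci_length = ci_len,
    post_mean = summary$mean,
    post_sd = summary$sd,
    hpd_lower = summary$hpd_lower,
    hpd_upper = summary$hpd_upper,
    hpd_length = hpd_len,
    length_diff = hpd_len - ci_len,
    se_diff = summary$sd - unname(fit$se),
    row.names = NULL
  )
  attr(res, "n_hpd_shorter") <- sum(hpd_len < ci_len)
  class(res) <- c("comparison_table", "data.frame")
  res
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("classical vs Bayesian comparison (%d of %d HPD intervals shorter than Wald)\n",
              attr(x, "n_hpd_shorter"), nrow(x)))
  print.data.frame(format.data.frame(x, digits = 4), row.names = FALSE)
  invisible(x)
}
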