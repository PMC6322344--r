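#!/usr/bin/env Rscript
# Stage 6: classical vs Bayesian comparison.
#
# Side-by-side table of the logistic MLE (estimate, SE, 95% Wald interval,
# length) and the posterior (mean, SD, 95% HPD, length) per slot. With the
# near-flat N(0, 1000) prior the two columns should be nearly identical;
# how often the HPD interval is the shorter one is reported as an observed
# count, not asserted as a rule.

library(cariesbayes)
cohort <- read_cohort("results/cohort.csv")
design <- encode_design(cohort)
mle <- fit_logistic(design)
draws <- read.csv("results/posterior_draws.csv", check.names = FALSE)
post <- summarize_posterior(as_posterior_samples(draws))

comparison <- compare_fits(mle, post)
print(comparison)
write.csv(comparison, "results/comparison.csv", row.names = FALSE)
message(sprintf("HPD shorter than Wald in %d of %d slots",
                attr(comparison, "n_hpd_shorter"), nrow(comparison)))
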