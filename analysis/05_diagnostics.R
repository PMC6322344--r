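#!/usr/bin/env Rscript
# Stage 5: convergence diagnostics on the stored draws.
#
# Gelman-Rubin R-hat per slot (pass: all < 1.1), lag-1 autocorrelation of
# the thinned draws (thinning at lag 50 should leave them near-independent),
# and exported ACF/density series so trace, density and autocorrelation
# plots are a thin optional layer over these numbers.

library(cariesbayes)
draws <- read.csv("results/posterior_draws.csv", check.names = FALSE)
samples <- as_posterior_samples(draws)

report <- convergence_report(samples, threshold = 1.1, max_lag = 20)
print(report)

write.csv(data.frame(report$psrf, acf_lag1 = unname(report$acf_lag1)),
          "results/diagnostics.csv", row.names = FALSE)
acf_tab <- do.call(rbind, lapply(names(report$acf), function(s) {
  data.frame(slot = s, report$acf[[s]])
}))
write.csv(acf_tab, "results/acf_series.csv", row.names = FALSE)
dens_tab <- do.call(rbind, lapply(names(report$density), function(s) {
  data.frame(slot = s, report$density[[s]])
}))
write.csv(dens_tab, "results/density_series.csv", row.names = FALSE)
message(if (report$pass) "all chains converged (R-hat < 1.1)" else
        "WARNING: convergence not reached")
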