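Package: cariesbayes
Title: Classical and Bayesian Logistic Regression for Dental Caries Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative risk-factor analysis of a binary dental-caries
    outcome against categorical covariates: descriptive cross-tabulation with
    crude odds and risk ratios, from-first-principles maximum-likelihood fits of
    logistic, log-binomial and robust (sandwich) Poisson regressions, a Bayesian
    logistic regression with independent normal priors sampled by adaptive
    Metropolis-within-Gibbs MCMC, convergence diagnostics (trace, density,
    autocorrelation, Gelman-Rubin), and side-by-side comparison of Wald
    confidence intervals with highest-posterior-density credible intervals.
    Includes a seeded synthetic-cohort generator emulating a retrospective
    clinic cohort of 6007 patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
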