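---
title: "Classical and Bayesian logistic regression for dental-caries risk factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical and Bayesian logistic regression for dental-caries risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dental caries is a multifactorial disease; in the cohort this package
models — 6007 patients of a dental clinic in Hawassa, Ethiopia, followed
retrospectively — the outcome of interest is dichotomous (natural caries,
y = 1, against non-natural caries, y = 0; prevalence 87%) and the candidate
risk factors are five categorical covariates: gender, place of residence,
region of origin, age group and teeth-cleaning habit. The analysis asks two
questions at once: *which factors are associated with the outcome*, and
*what does a Bayesian treatment of the same logistic model add over the
classical maximum-likelihood analysis* (posterior SDs vs standard errors,
HPD credible intervals vs Wald confidence intervals).

The patient-level data are not deposited. Everything in this package
therefore runs on two principled stand-ins, both first-class, tested code:

1. **A reconstruction from published counts.** The outcome-by-covariate
   cross-tabulation of the cohort is public, and every covariate's counts
   share the same outcome margin (778 non-natural / 5229 natural). A
   patient-level table can therefore be built whose five two-way
   (outcome × covariate) tables are all *exact*. Within an outcome stratum
   the covariate columns are filled independently in level order, so the
   joint covariate distribution is arbitrary: the reconstruction supports
   descriptive statistics and crude (single-covariate) measures exactly,
   and deliberately nothing more.
2. **A synthetic generator** (next section) for all multivariable work.

## Models

With reference coding (reference levels Female, Urban, Others, `<18`, No;
8 slots including the intercept), the classical models are

- logistic: $\mathrm{logit}(P_i) = x_i^\top\beta$, effects as odds ratios
  $e^{\beta_j}$;
- log-binomial: $\log(P_i) = x_i^\top\beta$, effects as risk ratios;
- Poisson with robust variance: Poisson log-link MLE applied to the binary
  outcome, effects as risk ratios, covariance by the HC0 sandwich
  $A^{-1}BA^{-1}$ with $A = X^\top\mathrm{diag}(\mu)X$ and
  $B = X^\top\mathrm{diag}((y-\mu)^2)X$.

The risk ratio is the preferred effect measure for a cohort design when the
outcome is common — here 87%, so the OR markedly overstates the RR (crude
gender OR 0.79 vs RR 0.97) — but the log-binomial model that estimates it
directly is fragile: its MLE can sit on the boundary of the constrained
parameter space ($P_i \le 1$) and fail to converge. The robust-Poisson model
is the standard fallback. All three are included so the comparison can be
made on one cohort.

The Bayesian model keeps the logistic likelihood
$L(\beta\mid y) = \prod_i p_i^{y_i}(1-p_i)^{1-y_i}$,
$p_i = \mathrm{logit}^{-1}(x_i^\top\beta)$, and places independent
$\beta_j \sim N(\mu_j, \sigma_j^2)$ priors on the coefficients, by default
$\mu_j = 0,\ \sigma_j^2 = 1000$: a deliberately near-flat prior, under which
the posterior should — and in the tests does — closely track the
maximum-likelihood fit. The unnormalized log-posterior is simply
log-likelihood + log-prior.

## The synthetic-data generator

`generator_config()` defaults *are* the study conditions: n = 6007;
covariate marginals equal to the published level totals (e.g. 2828/6007
female, 934/6007 SNNPR, 373/6007 teeth-cleaners); true coefficients equal to
the published Bayesian posterior means
(1.726, −0.2038, −0.3699, 0.4957, −0.484, −0.3205, −0.2887, 0.389); seed
20190107. Covariates are drawn **independently** from their marginals — the
published tables contain no information about their joint distribution, so
independence is the only defensible choice — and outcomes from
Bernoulli(plogis(x'β)).

One consequence is documented rather than hidden: under independent
marginals these coefficients imply a simulated prevalence near 0.78, below
the observed 0.87. The gap presumably reflects covariate dependence in the
real cohort. `calibrate_intercept()` exists for users who need
prevalence-matched cohorts (bisection on the intercept against a 10^5-draw
Monte-Carlo mean); it is opt-in so that default cohorts carry the literal
published coefficients.

What passing tests on these cohorts shows: the fitters and the sampler
recover known truths under the assumed model (correct likelihoods, correct
coverage, MLE/posterior agreement). What they cannot show: anything about
covariate dependence, confounding structure or model misspecification in
the real clinic population — in particular, the published multivariable
coefficients are not exactly reproducible by anyone without the raw data,
and this package does not pretend otherwise.

All generation runs on a single Mersenne-Twister stream seeded per call and
restores the caller's RNG state, so cohorts are byte-identical across runs
and platforms.

## The sampler

The posterior has no conjugate full conditionals, so the sampler is
Metropolis-within-Gibbs: one sweep updates the 8 coordinates in turn, each
with a random-walk Metropolis step (normal proposal) conditional on the
rest. Design choices that matter:

- **Inner updates.** Each coordinate receives 5 Metropolis tries per sweep
  (`inner_updates`). Repeated tries push each coordinate update toward an
  exact draw from its full conditional — i.e. toward genuine Gibbs
  sampling — which matters because dummy coding makes the intercept and
  slopes strongly correlated: with a single try per sweep the thinned
  (lag-50) draws of the intercept still had lag-1 autocorrelation ≈ 0.3,
  while with 5 tries all slots fall below 0.1.
- **Adaptation.** Per-coordinate proposal scales start at 2.4 × SE(MLE) and
  adapt in windows of 50 burn-in sweeps toward acceptance 0.44 (the
  one-dimensional random-walk optimum), then freeze, so the post-burn-in
  chain is time-homogeneous. Acceptance pinned at 0 or 1 after burn-in is
  an error, not a warning.
- **Initialization.** Chain 1 at the MLE, the others at MLE ± 2 SE per
  slot: overdispersed starts are what makes the Gelman–Rubin diagnostic
  informative.
- **Defaults.** 3 chains, burn-in 5000 sweeps, 10000 post-burn-in sweeps,
  thin 50 → 200 stored draws per chain, 600 pooled. All configurable.
- **Numerics.** Every density is computed in log space;
  $\log(1+e^\eta)$ uses the softplus form
  $\max(\eta,0)+\log(1+e^{-|\eta|})$, finite for $|\eta| = 500$ and beyond.
  Internally the design is collapsed to its ≤ 64 unique covariate patterns
  with success counts, so one likelihood evaluation costs a 64-element
  vector operation regardless of n.

## Summaries and diagnostics

- **Posterior summary** (per slot, pooled post-burn-in thinned draws): mean,
  SD, median; **MC error** by batch means with ⌊√N⌋ batches (the estimator
  is robust to residual autocorrelation and needs no spectral machinery);
  **95% HPD** as the shortest window among all windows of ⌈0.95 N⌉
  consecutive sorted draws. Fewer than 100 pooled draws is an error —
  summaries that thin would be noise.
- **Gelman–Rubin.** With m chains of n stored draws, W is the mean
  within-chain variance and B = n·var(chain means). The package uses the
  pooled-variance form V = W + B/n, so that
  $\hat R = \sqrt{V/W} = \sqrt{1 + B/(nW)}$ is exactly 1 for identical
  chains and never below 1; it differs from the classic
  $(n-1)/n$-deflated form only at order 1/n, and the deflated form has the
  awkward property of dipping below 1 for agreeing chains. Threshold 1.1,
  the conventional cutoff of this diagnostic's era. No rank-normalization
  and no split chains, matching the original statistic.
- **Autocorrelation.** Sample ACF with overall-mean centering and lag-0
  normalization; a variance-zero series is defined as ACF 1 at lag 0 and 0
  elsewhere. The report's per-slot lag-1 ACF of the thinned draws is the
  *mean* across chains: each chain contributes only 200 draws, so a single
  chain's ACF estimate carries noise of SD ≈ 0.07, and a maximum over
  chains would exceed any sensible cutoff even for independent draws.
- **Density series** are exported as numbers (Gaussian kernel, Silverman's
  rule bandwidth) so that trace/density/ACF plots are an optional layer
  over tested CSV output, not a precondition for checking convergence.

## Classical-fit numerics

Newton–Raphson with step-halving (max 20 halvings) on the score, tolerance
1e-8 on the maximum absolute gradient component, 100 iterations. Starting
values: zeros for logistic; intercept log(mean(y)) with zero slopes for the
log-link models (an interior start by construction). A coefficient
magnitude above 30 — beyond any plausible epidemiological effect — raises an
explicit complete-separation error. For the logistic model the SEs are the
inverse observed information (which, for the canonical logit link, equals
the expected information). For the log-binomial model the SEs use the
expected (Fisher) information, w = p/(1−p): the observed information under
the log link is degenerate on records with y = 1, and the expected form is
what standard GLM software reports. Crude 2×2 measures raise an error on a
zero cell unless the Haldane–Anscombe +0.5 correction is explicitly
requested — silent continuity corrections hide data problems.

On a saturated categorical design the robust-Poisson and log-binomial fits
coincide not only in point estimates but in SEs (the HC0 sandwich collapses
cell-wise to the binomial variance (1−p)/(np)); they separate on
non-saturated designs, where the sandwich correctly shrinks the naive
Poisson SEs for a common outcome.

## Problem sizes used in the tests

The package's own verification choices: the headline Bayesian run uses the
full default configuration (n = 6007, 3 chains, thin 50). Parameter
recovery uses 20 replicate cohorts at n = 6007 with a lighter per-replicate
sampler (2 chains, 1000 burn-in, 5000 sweeps thinned at 25, 2 inner tries)
— coverage of a 95% interval is an aggregate property over 160
slot×replicate cases and does not need 600 draws per replicate to assess.
Closed-form and saturated-design checks run at the published margins
(5229/6007 and the gender 2×2).

## Known limitations

- The reconstruction from published counts fixes all two-way
  outcome×covariate tables but invents the joint covariate distribution;
  crude measures from it are exact, multivariable fits from it are not
  meaningful and are never used.
- The generator's independence assumption undershoots the observed
  prevalence (see above); intercept calibration is available but changes
  the literal intercept.
- The sampler is a general-purpose Metropolis-within-Gibbs; no Pólya-Gamma
  augmentation or gradient-based sampling, which would mix faster but
  belong to a different modeling toolkit.
- Whether the HPD interval is shorter than the Wald interval is reported as
  an observed per-slot count. With σ² = 1000 the two intervals are
  near-identical and the direction flips with Monte-Carlo noise; the
  package asserts no theorem about it.
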