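---
title: "Bayesian models for N-of-1 trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian models for N-of-1 trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nof1bayes)
```

This vignette documents the statistical models the package implements,
the numerical choices behind the sampler, and the design decisions made
where several reasonable options existed. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` compute.

## Single-trial models

An N-of-1 trial assigns one participant to K treatments in randomized
periods and records an outcome repeatedly. The package's first-level
model for a continuous outcome is

$$Y_j = m + \sum_{k \ne 1}\delta_k 1\{A_j = k\} + \beta t_j + e_j,$$

with reference level $m$ (or arm means $m_k$; the two parameterizations
are connected by $m_k = m + \delta_k$ and both are supported), optional
linear trend $\beta$ per week, and one of three error structures:

* independent errors $e_j \sim N(0, \sigma^2)$;
* stationary AR(1) errors $e_j = \rho_e e_{j-1} + \varepsilon_j$, so
  each outcome is marginally $N(M_j,\, \sigma^2/(1-\rho_e^2))$;
* lagged-outcome autocorrelation, adding $\rho_Y Y_{j-1}$ to the mean.
  Here $\delta_k$ is conditional on the previous outcome; no marginal
  effect is derived, and summaries report the conditional coefficient
  (the distinction is easy to miss and is flagged in the docs).

Bernoulli-logit and Poisson-log outcomes use the same linear predictor
through a link function; they are restricted to independent
observations because a latent-variable treatment of autocorrelation for
discrete data is out of scope.

**Likelihood modes.** The default `"exact"` mode evaluates the joint
Gaussian density by the AR(1) conditional decomposition: the first
observation from its stationary marginal, each later observation
conditionally normal given the previous *observed* one. Gaps (washout
trimming, missing rows) are handled with lag-aware moments — mean decay
$\rho^{\Delta}$ and conditional variance
$v(1-\rho^{2\Delta})$ with $v = \sigma^2/(1-\rho_e^2)$ — which by the
Markov property is the exact marginal likelihood of the observed subset
(negative $\rho_e$ requires integer lags, which weekly cadences give).
A `"paper_product"` mode instead multiplies the stationary marginals,
ignoring cross-time correlation; it exists because that product form is
how the posterior is sometimes written out, but the exact mode is the
default since correct imputation conditionals require the joint density.
The two agree exactly at $\rho_e = 0$, which the tests assert.

**Priors.** `default_priors()` encodes noninformative-but-bounded
choices tailored to bounded scales: treatment means uniform over the
declared outcome range (34–78 for the child-report pain-interference
T-score, 38–78 for parent report), contrasts uniform over plus/minus the
scale width (hence U(−44, 44) on that scale), $\rho \sim U(-1, 1)$,
$\sigma \sim U(0, 1000)$, and a vague Normal(0, 10^6) on trend slopes.
On unbounded scales the means fall back to the vague normal. Bounded
uniforms on means become truncation limits in the sampler. When a trend
is fit, the time covariate is centered at the trial's mean observed time
so the intercept and slope decorrelate; the slope is reported per week
on the original scale.

## The sampler

The engine is a componentwise Metropolis-within-Gibbs sampler over a
"term graph": the log posterior is a sum of scalar terms (per-individual
likelihoods, random-effect densities, priors) and each parameter knows
which terms its full conditional involves, so an update only recomputes
what changed.

* **Gaussian conditionals** (means, contrasts, trend slopes, random
  effects, hyper-means, and missing-outcome slots under data
  augmentation in normal models) are drawn by exact Gibbs. The
  conditional's mean and variance are obtained from a three-point local
  quadratic fit of the log density; for a quadratic function the fit is
  exact for any step, so this is a closed-form conjugate draw without
  symbolic bookkeeping. Draws are inverse-CDF truncated to the declared
  support, which is how bounded-uniform priors act. If the fitted
  curvature is not usable (flat directions early in warmup), the update
  falls back to a Metropolis step.
* **Non-Gaussian conditionals** — autocorrelations (Fisher-z scale),
  standard deviations (log scale), the intercept–effect correlation
  (Fisher-z with positive-definiteness rejection), and all parameters of
  discrete-outcome models — use adaptive random-walk Metropolis with the
  transform Jacobians in the acceptance ratio. Step sizes adapt toward a
  0.44 acceptance rate during warmup only and are frozen afterwards, so
  the post-warmup chain satisfies detailed balance.

Defaults are 4 chains of 2500 warmup + 2500 draws with an R-hat
threshold of 1.05; all are configurable, and effective sample sizes
(Geyer initial positive sequence) are reported so users can judge chain
length — the hierarchical effect means mix the slowest, and short
exploratory chains should be checked against `gelman_rubin()`.
Each chain derives a deterministic sub-seed from the configured seed, so
runs reproduce exactly. Convergence uses split-chain R-hat (a single
chain yields the split-half statistic); chains stuck at distinct
constants give an infinite value, and an all-constant parameter is
reported as 1 with a degeneracy warning.

**Summaries.** Point estimates are posterior medians; intervals are
central empirical quantiles (linear interpolation between order
statistics, R's default type 7 — the convention is fixed and documented
because results at small draw counts depend on it).

## Multilevel aggregation

Each family of first-level parameters (intercepts, effects, trends,
autocorrelations) can be *common*, *fixed*, or *random*; residual
variances only common or fixed, because a hierarchy on variances is
under-identified at typical N-of-1 sizes and easiest treated as fixed.
Random effects get normal second-level laws; autocorrelations are first
mapped by Fisher-z. The multilevel assembly uses the contrast
parameterization, which is the natural scale for the effect hierarchy.

The structured covariance for $(\mu_i, \delta_{i2},\dots,\delta_{iK})$
puts correlation $\rho_{\mu\delta}$ between intercept and every effect
and correlation exactly 0.5 between effects: with a constant treatment
variance every pairwise contrast must have equal variance, which pins
the effect-block correlation at 1/2. The effect block is implemented as
$(K-1)\times(K-1)$ over the contrasts — the vector being modeled has
$K-1$ effect entries — and every hyperparameter update attempts a
Cholesky factorization, rejecting proposals that leave the admissible
region ($\rho_{\mu\delta}^2 < (1 + (K-2)/2)/(K-1)$), since no closed
bound needs to be assumed that way.

Subgroup structure enters as regressions on the effect means,
$d_k = d_{0k} + \sum_j d_{jk} x_{jk}$; `subgroup_effect()` turns the
posterior draws into per-setting effects and their difference so
probabilities like "improvement larger for girls than boys" are one
`prob_event()` call. Within-individual covariates enter the first-level
mean with common or fixed coefficients.

**Carryover** is modeled as a covariate $z = 2^{-(t - t^*)/h}$ decaying
from the crossover time $t^*$ with half-life $h$, its coefficient tied
to the carried-over treatment's effect (total effect
$\delta(1+z)$ immediately after crossover into the reference
treatment). Only configured treatment-pair transitions generate the
covariate, and a per-individual design-matrix rank check warns when the
carryover column is confounded with treatment or sequence (as in
strictly alternating designs) instead of silently fitting it. The
fully enumerated crossover-pair parameterization (2 × K-choose-2
separate carryover parameters) is not implemented; only the covariate
form is.

## Missing data

*Missing at random*: missing outcome rows are design slots. In
single-trial fits they can be treated as model parameters — data
augmentation falls out of the Gibbs machinery, since a missing value's
conditional under the AR(1) model is Gaussian — and
`impute_mar_draw()`/`mar_conditional_moments()` expose the closed-form
conditionals (nearest observed neighbor each side, lag-aware weights)
for direct use. Multiple missing values are drawn left to right so the
joint draw is exact. Imputed bounded outcomes are truncated to the scale
range, with truncations counted, because an unbounded draw could leave
the instrument's range.

*Missing not at random*: following the observation that withdrawal marks
lack of benefit, informative dropout is operationalized by stratifying on
completion behavior — full completers, early completers (one completed
crossover), withdrawals — fitting the stratum's own multilevel model
(fixed intercepts, random effects, common $\rho_e$ and $\sigma$) on its
observed data, and imputing each individual's missing slots from their
own stratum's posterior, using M evenly spaced posterior draws. Rows are
first expanded so everyone meets minimum-measurement rules (default: at
least one baseline and six per experimental period, matching a
seven-measurement post-washout period). Per-imputation estimates are
combined by Rubin's rules; the interval uses the standard small-M
degrees-of-freedom adjustment $(M-1)(1 + \bar U/((1+1/M)B))^2$, stated
here explicitly because "Rubin's rules" alone leaves the reference
distribution ambiguous.

A deliberate limitation: individuals in a stratum that never received a
treatment (withdrawals who stopped before the second diet) have that
effect informed only by the hierarchy and priors, and imputations for
such periods are correspondingly diffuse. This is visible in the tests,
which check imputed values only for treatments the stratum observed.

## Decision summaries

`classify_responder()` encodes the responder rule: probability of
clinically meaningful improvement above 0.5 and probability of meaningful
worsening below 0.1, with the minimum clinically important difference
defaulting to 3 points (the pain-interference convention). Both
improvement and worsening are "beyond the MCID" in their respective
directions. The benefit direction is a per-outcome flag: for pain
interference lower is better, so improvement is a difference below
$-3$ and the benefit column reports $\Pr(\text{difference} < 0)$ —
published tables for this outcome define improvement as a negative
difference even where the surrounding prose describes score increases as
improvement, and the flag (default `"lower"`) resolves that ambiguity
explicitly rather than hard-coding either reading.

`benefit_harm_table()` reports median, central interval and
$\Pr(<0)$ per comparison. Comparing a treatment with itself yields a
degenerate zero difference (probability 0 of being below zero), not 0.5:
the draws are identical, and we do not inject artificial independence.
Posterior-predictive checks use
$\Pr(T(y^{rep},\Theta) \ge T(y,\Theta) \mid y)$ with ties counted as
exceedance, exactly as the defining inequality reads, so a statistic
constant in $y$ gives 1.

## The synthetic-data generator

`simulate_population()` emulates the structure of a two-diet pediatric
crossover study: a 2-week usual-diet baseline, four 8-week experimental
periods in ABAB or BABA order, weekly bounded outcomes with AR(1) noise,
and three completion strata with base probabilities 21/54, 9/54, 24/54.
Generator defaults are the study conditions: mean diet effects of −3
points, effect heterogeneity $\sigma_\delta = 2$, autocorrelation 0.4,
residual SD 5, intercept mean 50 with SD 5 (a T-score instrument has
population mean 50 and SD 10; within-cohort spread is plausibly about
half that), no trend. With a single experimental diet (K = 2) the A/B
sequence letters map to diet/reference alternation instead of the two
diets. Withdrawals stop during the first experimental period, so the
stratum labels recorded by the generator agree exactly with the
data-driven classification rule; real withdrawals could also stop
mid-second-period, a pattern the completion rule cannot distinguish from
early completion and which the generator therefore does not produce.
A positive `mnar_shift` (default 1) multiplies the withdrawal weight by
$\exp(\text{shift} \times (\delta_{i2} - d_2)/\sigma_\delta)$, making
dropout informative — less benefit, more withdrawal — with magnitude as
a knob since no dropout model is being reproduced quantitatively.
Intermittent missingness is 10% at random.

What the generator does *not* emulate: early or delayed crossovers
(period boundaries come from the declared design), site and disease-type
stratification, reporter switching within an individual, adherence
drift, or floor/ceiling clustering beyond simple truncation (truncated
draws are counted; recovery studies use wide or absent bounds so
truncation is negligible). Passing recovery tests on this generator
therefore demonstrates correctness of the inference machinery under the
declared model, not robustness to those real-data features.

## Problem sizes used by the test suite

The quantitative checks run at sizes chosen to give informative Monte
Carlo precision on a single CPU: likelihood-vs-oracle agreement on 200
random instances up to n = 8; parameter recovery as the mean posterior
median of $d_2$ over 20 replicates of 30 individuals × 30 weekly
measurements (conditions $d_2 = -3$, $\sigma_\delta = 2$,
$\rho_e = 0.4$, $\sigma = 5$, fixed intercepts); interval coverage over
100 micro-replicates of 10 individuals × 11 measurements;
posterior-predictive calibration over 200 replicates of a 12-point
trial; oracle agreement for imputation conditionals and Rubin pooling at
tolerances $10^{-8}$ and $10^{-12}$. Short exploratory chains in unit
tests raise the R-hat gate accordingly; the acceptance-grade checks rely
on closed forms or Monte-Carlo-error-scaled tolerances.

## Known limitations

* No categorical (multinomial) outcome models and no latent-variable
  autocorrelation for discrete outcomes.
* No network meta-analysis across heterogeneous treatment sets.
* The multilevel assembly is contrast-parameterized; arm-based
  multilevel models would need a reparameterization layer.
* Random-effect location/scale sampling is single-site Gibbs, which can
  mix slowly when $\sigma_\delta$ is near zero; effective sample sizes
  are reported so users can lengthen chains.
* Period labels must be supplied in the input; the package does not
  infer period boundaries from treatment switches, because designs with
  participant-chosen crossover times make such inference unreliable.
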