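# nof1bayes

Bayesian analysis of N-of-1 trials — single-participant crossover
experiments in which one person receives two or more treatments in
randomized periods — and of collections of such trials run under a shared
design. The package is aimed at biostatisticians analyzing
patient-reported outcome series (e.g. weekly PROMIS T-scores in a
diet-crossover study for pediatric IBD) who need per-individual treatment
effects, population-average effects with heterogeneity, and
decision-ready summaries such as the probability that a treatment helps a
given person.

## Models

For one individual, the outcome at measurement *j* follows

> Y_j = m + Σ_{k≠1} δ_k 1{A_j = k} + β t_j + e_j,  e_j = ρ_e e_{j−1} + ε_j,  ε_j ~ N(0, σ²)

with a reference-treatment level *m*, treatment contrasts δ_k (or
equivalently arm means m_k), optional linear trend β, and stationary
AR(1) errors, so that marginally Y_j ~ N(m + δ_k + β t_j, σ²/(1−ρ_e²)).
Variants: lagged-outcome autocorrelation (Y_{j−1} as a predictor),
Bernoulli-logit and Poisson-log outcomes, and an exponentially decaying
carryover covariate z = 2^(−elapsed/half-life) whose coefficient is tied
to the carried-over treatment's effect.

Trials are combined in a multilevel model: each individual's parameters
are **common** (shared), **fixed** (independent nuisance parameters), or
**random**, e.g. δ_ik ~ N(d_k, σ_δ²), with a structured
intercept–effect covariance Σ_μδ whose effect block has pairwise
correlation exactly 0.5 (forced by contrast consistency under a constant
treatment variance), Fisher-z normal random effects for autocorrelations,
and subgroup regressions d_k = d_0k + Σ_j d_jk x_jk.

Inference is by a built-in Metropolis-within-Gibbs sampler: exact Gibbs
draws for parameters with Gaussian full conditionals (means, contrasts,
random effects, missing-outcome slots under data augmentation) and
adaptive random-walk Metropolis on transformed scales for
autocorrelations (Fisher-z) and standard deviations (log). Missing
outcomes are either imputed inside the sampler (missing at random) or by
completion-stratum-specific multiple imputation with Rubin's-rules
pooling when dropout is informative.

## Worked example

Simulate a diet-trial-like population (2-week usual-diet baseline, then
ABAB/BABA sequences of two diets in 8-week periods, weekly bounded
outcomes, AR(1) noise, informative dropout), trim the washout week,
and meta-analyze:

```r
library(nof1bayes)

sim <- simulate_population(hyper_params(d = c(-3, -2.5)), n = 12,
                           seed = 42, bounds = c(34, 78))
trial_data <- apply_washout(sim$data, n_drop = 1)

fit <- fit_meta(trial_data,
                config = sampler_config(chains = 2, warmup = 2000,
                                        draws = 2500, seed = 1))
tidy(fit) |>
  dplyr::filter(parameter %in% c("d[2]", "d[3]", "rho", "sigma", "sigma_delta"))
#> # A tibble: 5 × 8
#>   parameter   median  lower  upper   mean   ess  rhat converged
#>   <chr>        <dbl>  <dbl>  <dbl>  <dbl> <dbl> <dbl> <lgl>
#> 1 d[2]        -5.30  -9.20  -1.49  -5.30    242  1.01 TRUE
#> 2 d[3]        -4.50  -8.08  -0.904 -4.51    216  1.01 TRUE
#> 3 sigma_delta  2.83   1.24   5.67   2.99    129  1.00 TRUE
#> 4 rho          0.294  0.131  0.459  0.294   828  1.00 TRUE
#> 5 sigma        5.07   4.56   5.64   5.08    922  1.00 TRUE

benefit_harm_table(fit, list("SCD v UD" = c(2, 1), "MSCD v UD" = c(3, 1),
                             "SCD v MSCD" = c(2, 3)))
#> # A tibble: 3 × 8
#>   comparison median lower  upper pr_less_0 p_improvement p_worsening responder
#>   <chr>       <dbl> <dbl>  <dbl>     <dbl>         <dbl>       <dbl> <lgl>
#> 1 SCD v UD   -5.30  -9.20 -1.49      0.997         0.888      0      TRUE
#> 2 MSCD v UD  -4.50  -8.08 -0.904     0.993         0.797      0.0004 TRUE
#> 3 SCD v MSCD -0.801 -4.54  3.14      0.681         0.106      0.0284 FALSE
```

`d[2]` and `d[3]` are the population mean effects of the two diets
versus usual diet (lower = less pain interference); `rho` and `sigma`
are the shared autocorrelation and residual SD; `sigma_delta` the
between-individual effect SD. The benefit/harm table gives the posterior
median difference, 95% credible interval, the probability the difference
is below zero, and the probabilities of clinically meaningful (≥ 3-point)
improvement and worsening that drive responder classification. Note the
population effects here overshoot the generating value of −3: the
simulated dropout is informative (less benefit → earlier withdrawal), and
this observed-data analysis does not correct for it — that is what
`impute_mnar_by_group()` + `fit_imputed()` are for.

Per-individual fits, posterior predictive checks and imputation follow
the same pattern: `fit_single()`, `ppc_pvalue()`, `impute_mnar_by_group()`,
`rubin_pool()`. Reproducible end-to-end runs are driven by a YAML config
through `cmd_fit_single()` / `cmd_fit_meta()` / `cmd_simulate()` /
`cmd_impute()` or the `exec/nof1` script.

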