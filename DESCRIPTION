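Package: nof1bayes
Title: Bayesian Analysis of N-of-1 Trials and Their Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and tools for single-participant (N-of-1) crossover
    trials with continuous, binary or count outcomes: arm- and
    contrast-based treatment means, linear trend, AR(1) autocorrelated
    errors or outcomes, and carryover covariates with exponential decay.
    Inference is by a built-in Metropolis-within-Gibbs sampler with
    convergence diagnostics and posterior summaries.  Trials sharing a
    design can be combined in a Bayesian multilevel meta-analysis with
    common, fixed or random individual-level parameters, a structured
    intercept-effect covariance, and Fisher-z random effects for
    autocorrelations.  Missing outcomes are imputed inside the sampler
    under missing-at-random, or by completion-stratum-specific multiple
    imputation with Rubin's-rules pooling when missingness is informative.
    Decision summaries include credible intervals, probabilities of
    benefit and harm, and responder classification, plus a simulator for
    diet-trial-like designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
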