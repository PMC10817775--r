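#' Specify a single-trial model
#'
#' Chooses the mean structure, trend, autocorrelation form, outcome family
#' and likelihood mode for one N-of-1 trial.
#'
#' @param parameterization `"arm"` (a mean per treatment, `m_k`) or
#'   `"contrast"` (reference mean `m` plus contrasts `delta_k`, k = 2..K).
#' @param trend `"none"` or `"linear"` (slope `beta` per week).
#' @param autocorrelation `"none"`, `"ar_errors"` (AR(1) errors, the
#'   stationary-error model) or `"ar_outcomes"` (lagged-outcome regression;
#'   treatment effects are then conditional on the previous outcome).
#' @param family `"normal"`, `"bernoulli_logit"` or `"poisson_log"`.  The
#'   discrete families require `autocorrelation = "none"`.
#' @param carryover `"none"` or `"half_life"` (exponentially decaying
#'   carryover covariate, see [carryover_covariate()]).
#' @param likelihood_mode `"exact"` (joint density via the AR(1) conditional
#'   decomposition; the default) or `"paper_product"` (product of stationary
#'   marginals, ignoring cross-time correlation).
#' @return A list of class `nof1_model_spec`.
#' @export
model_spec <- function(parameterization = c("arm", "contrast"),
                       trend = c("none", "linear"),
                       autocorrelation = c("none", "ar_errors", "ar_outcomes"),
                       family = c("normal", "bernoulli_logit", "poisson_log"),
                       carryover = c("none", "half_life"),
                       likelihood_mode = c("exact", "paper_product")) {
  spec <- list(
    parameterization = match.arg(parameterization),
    trend = match.arg(trend),
    autocorrelation = match.arg(autocorrelation),
    family = match.arg(family),
    carryover = match.arg(carryover),
    likelihood_mode = match.arg(likelihood_mode)
  )
  if (spec$family != "normal" && spec$autocorrelation != "none") {
    stop("discrete families require autocorrelation = \"none\"", call. = FALSE)
  }
  structure(spec, class = "nof1_model_spec")
}

#' Prior building blocks
#'
#' Small constructors for the prior families the sampler understands.
#' `prior_uniform()` gives a flat density on `(lower, upper)`;
#' `prior_normal()` a normal density; `prior_flat()` an improper flat prior
#' on the whole real line.
#'
#' @param lower,upper Support bounds.
#' @param mean,sd Normal prior moments.
#' @return A list describing the prior.
#' @export
prior_uniform <- function(lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  list(dist = "uniform", lower = lower, upper = upper)
}

#' @rdname prior_uniform
#' @export
prior_normal <- function(mean = 0, sd = 1000) {
  stopifnot(sd > 0)
  list(dist = "normal", mean = mean, sd = sd)
}

#' @rdname prior_uniform
#' @export
prior_flat <- function() list(dist = "flat")

#' Default noninformative priors for a bounded outcome scale
#'
#' Treatment means get a flat prior over the declared outcome range,
#' contrasts a flat prior over `(-(upper - lower), upper - lower)` (the
#' largest difference the scale allows), autocorrelations a Uniform(-1, 1),
#' the residual standard deviation a Uniform(0, 1000), and the trend slope a
#' vague Normal(0, 10^6).  For the pain-interference scale this reproduces
#' the U(34, 78) / U(38, 78) mean priors and the U(-44, 44) contrast prior.
#'
#' @param spec An [model_spec()] object.
#' @param bounds Length-2 numeric `c(lower, upper)` outcome bounds, or `NULL`
#'   for an unbounded scale (means then get the vague normal prior).
#' @return A named list of priors (class `nof1_prior_spec`) keyed by parameter
#'   role: `mean`, `contrast`, `beta`, `rho`, `sigma`.
#' @export
default_priors <- function(spec = model_spec(), bounds = c(34, 78)) {
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2, all(is.finite(bounds)))
    range <- bounds[2] - bounds[1]
    mean_prior <- prior_uniform(bounds[1], bounds[2])
    contrast_prior <- prior_uniform(-range, range)
  } else {
    mean_prior <- prior_normal(0, 1000)
    contrast_prior <- prior_normal(0, 1000)
  }
  structure(list(
    mean = mean_prior,
    contrast = contrast_prior,
    beta = prior_normal(0, 1000),
    rho = prior_uniform(-1, 1),
    sigma = prior_uniform(0, 1000)
  ), class = "nof1_prior_spec")
}

prior_logdens <- function(prior, x) {
  switch(prior$dist,
    uniform = ifelse(x >= prior$lower & x <= prior$upper,
                     -log(prior$upper - prior$lower), -Inf),
    normal = stats::dnorm(x, prior$mean, prior$sd, log = TRUE),
    flat = 0
  )
}

prior_support <- function(prior) {
  switch(prior$dist,
    uniform = c(prior$lower, prior$upper),
    c(-Inf, Inf)
  )
}
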