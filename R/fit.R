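#' Fit a single N-of-1 trial
#'
#' Assembles and samples the posterior for one individual.  The default
#' model mirrors a typical single-trial analysis of a bounded pain outcome:
#' arm-based treatment means, AR(1) errors, no trend, with missing outcomes
#' imputed as model parameters.
#'
#' @param data An [nof1_data] tibble.
#' @param id Individual to fit (required when `data` has several).
#' @param spec A [model_spec()].
#' @param priors Priors; default [default_priors()] with the individual's
#'   declared outcome bounds.
#' @param config A [sampler_config()].
#' @param impute_missing Treat missing outcome rows as parameters.
#' @return An `nof1_draws` object.
#' @export
fit_single <- function(data, id = NULL,
                       spec = model_spec("arm",
                                         autocorrelation = "ar_errors"),
                       priors = NULL, config = sampler_config(),
                       impute_missing = TRUE) {
  df <- tibble::as_tibble(data)
  ids <- unique(df$id)
  if (is.null(id)) {
    if (length(ids) > 1) stop("several individuals present; supply `id`",
                              call. = FALSE)
    id <- ids
  }
  if (!id %in% ids) stop("unknown individual: ", id, call. = FALSE)
  sub <- df[df$id == id, ]
  trial <- nof1_data(sub, k = n_treatments(data), bounds = attr(data, "bounds"))
  if (is.null(priors)) {
    bl <- bounds_for(sub, attr(data, "bounds"))
    b <- if (all(is.finite(c(bl$lower, bl$upper))))
      c(min(bl$lower), max(bl$upper)) else NULL
    priors <- default_priors(spec, b)
  }
  model <- assemble_single_trial(trial, spec, priors,
                                 impute_missing = impute_missing)
  sample_posterior(model, config)
}

#' Fit a multilevel meta-analysis of N-of-1 trials
#'
#' Assembles and samples the posterior for a collection of trials.  The
#' default second-level structure is the stratified meta-analysis
#' configuration: fixed intercepts (implicitly adjusting for stratification
#' factors), random treatment effects, a common autocorrelation and a
#' common residual variance, analyzing observed outcomes only.
#'
#' @param data An [nof1_data] tibble with two or more individuals.
#' @param spec A [model_spec()] (contrast parameterization).
#' @param level A [level_spec()].
#' @param priors Priors; default [default_priors()] with the pooled outcome
#'   bounds.
#' @param config A [sampler_config()].
#' @return An `nof1_draws` object.
#' @export
fit_meta <- function(data,
                     spec = model_spec("contrast",
                                       autocorrelation = "ar_errors"),
                     level = level_spec(intercepts = "fixed",
                                        effects = "random",
                                        correlations = "common",
                                        variances = "common"),
                     priors = NULL, config = sampler_config()) {
  if (dplyr::n_distinct(tibble::as_tibble(data)$id) < 2) {
    stop("meta-analysis needs at least two individuals", call. = FALSE)
  }
  if (is.null(priors)) priors <- default_priors(spec, stratum_bounds(data))
  model <- assemble_multilevel(data, spec, level, priors)
  sample_posterior(model, config)
}
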