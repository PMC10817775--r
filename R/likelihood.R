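#' Single-trial model parameters
#'
#' Bundles the parameters of a single-trial model.  Use either `m` + `delta`
#' (contrast form: reference mean plus contrasts for treatments 2..K) or `mk`
#' (arm form: one mean per treatment).
#'
#' @param m Reference-treatment mean (contrast form).
#' @param delta Numeric vector of contrasts `delta_k`, k = 2..K (contrast
#'   form); may be empty for K = 2 models written in arm form.
#' @param mk Numeric vector of K arm means (arm form).
#' @param beta Linear trend slope per week (0 = no trend).
#' @param rho_e AR(1) error autocorrelation in (-1, 1).
#' @param rho_y AR(1) outcome autocorrelation in (-1, 1).
#' @param sigma2 Residual variance (> 0).
#' @return A list of class `nof1_params`.
#' @export
single_trial_params <- function(m = NULL, delta = numeric(), mk = NULL,
                                beta = 0, rho_e = 0, rho_y = 0, sigma2 = 1) {
  if (is.null(m) == is.null(mk)) {
    stop("supply exactly one of `m` (contrast form) or `mk` (arm form)",
         call. = FALSE)
  }
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (abs(rho_e) >= 1 || abs(rho_y) >= 1) {
    stop("autocorrelation must lie in (-1, 1): nonstationary", call. = FALSE)
  }
  structure(list(m = m, delta = delta, mk = mk, beta = beta,
                 rho_e = rho_e, rho_y = rho_y, sigma2 = sigma2),
            class = "nof1_params")
}

# mean path M_j = intercept + treatment effect + beta * t (+ carryover)
# trt: integer codes; z_carry/carry_from optional carryover covariate columns
mean_path <- function(params, spec, time, trt,
                      z_carry = NULL, carry_from = NULL) {
  if (spec$parameterization == "arm") {
    mk <- params$mk
    mu <- mk[trt]
    dk <- mk - mk[1]              # effects relative to reference
  } else {
    dfull <- c(0, params$delta)
    mu <- params$m + dfull[trt]
    dk <- dfull
  }
  if (spec$trend == "linear") mu <- mu + params$beta * time
  if (spec$carryover == "half_life" && !is.null(z_carry)) {
    carry_eff <- ifelse(!is.na(carry_from) & carry_from > 1L,
                        dk[pmax(carry_from, 1L)], 0)
    carry_eff[is.na(carry_eff)] <- 0
    mu <- mu + carry_eff * z_carry
  }
  mu
}

#' Marginal mean and variance of one measurement
#'
#' Under the stationary AR(1)-error model each outcome is marginally normal
#' with mean `M_j = m + delta_k + beta * t` and variance
#' `sigma^2 / (1 - rho_e^2)` (just `sigma^2` without autocorrelation).
#'
#' @param params A [single_trial_params()] object.
#' @param spec A [model_spec()] (normal family, `ar_errors` or `none`).
#' @param time Measurement time (weeks).
#' @param treatment Treatment code.
#' @return A named list with `mean` and `variance`.
#' @export
marginal_moments <- function(params, spec, time, treatment) {
  stopifnot(spec$family == "normal",
            spec$autocorrelation %in% c("none", "ar_errors"))
  if (abs(params$rho_e) >= 1) stop("nonstationary: |rho_e| >= 1", call. = FALSE)
  mu <- mean_path(params, spec, time, as.integer(treatment))
  v <- if (spec$autocorrelation == "ar_errors") {
    params$sigma2 / (1 - params$rho_e^2)
  } else {
    params$sigma2
  }
  list(mean = mu, variance = v)
}

# strip a trial into plain vectors once (fast path for the sampler)
trial_arrays <- function(trial) {
  df <- tibble::as_tibble(trial)
  list(
    y = df$value,
    t = df$time,
    trt = df$treatment,
    obs = !is.na(df$value),
    z_carry = if ("z_carry" %in% names(df)) df$z_carry,
    carry_from = if ("carry_from" %in% names(df)) as.integer(df$carry_from)
  )
}

#' Log-likelihood of a single trial
#'
#' Joint log density of the observed outcomes of one trial under the chosen
#' model.  In `"exact"` mode the AR(1)-error model is evaluated by its
#' conditional decomposition: the first observation from its stationary
#' marginal, each later one conditionally normal given the previous observed
#' outcome, with lag-aware moments (`rho^lag` mean decay) so that washout
#' gaps and missing rows are marginalized exactly.  In `"paper_product"`
#' mode the likelihood is the literal product of stationary marginals.  The
#' lagged-outcome model (`ar_outcomes`) is evaluated by a forward pass that
#' marginalizes unobserved intermediate outcomes.
#'
#' @inheritParams marginal_moments
#' @param trial An [nof1_data] tibble for one individual (rows with missing
#'   `value` are skipped/marginalized).
#' @return The log-likelihood (scalar).
#' @export
loglik <- function(params, spec, trial) {
  a <- trial_arrays(trial)
  if (spec$family != "normal") return(glm_loglik(params, spec, trial))
  if (!any(a$obs)) stop("trial has no non-missing outcome", call. = FALSE)
  if (any(!is.finite(a$y[a$obs]))) stop("nonfinite outcome value", call. = FALSE)
  mu <- mean_path(params, spec, a$t, a$trt, a$z_carry, a$carry_from)
  s2 <- params$sigma2

  if (spec$autocorrelation == "none") {
    return(sum(stats::dnorm(a$y[a$obs], mu[a$obs], sqrt(s2), log = TRUE)))
  }
  if (spec$autocorrelation == "ar_errors") {
    rho <- params$rho_e
    if (abs(rho) >= 1) stop("nonstationary: |rho_e| >= 1", call. = FALSE)
    v <- s2 / (1 - rho^2)
    r <- a$y[a$obs] - mu[a$obs]
    if (spec$likelihood_mode == "paper_product") {
      return(sum(stats::dnorm(r, 0, sqrt(v), log = TRUE)))
    }
    n <- length(r)
    if (n == 1) return(stats::dnorm(r, 0, sqrt(v), log = TRUE))
    dt <- diff(a$t[a$obs])
    rho_dt <- sign(rho)^dt * abs(rho)^dt  # exact for integer lags
    cond_var <- v * (1 - rho_dt^2)
    return(stats::dnorm(r[1], 0, sqrt(v), log = TRUE) +
             sum(stats::dnorm(r[-1], rho_dt * r[-n], sqrt(cond_var),
                              log = TRUE)))
  }
  # ar_outcomes: Y_j = M_j + rho_y * Y_{j-1} + eps, forward filter over rows
  rho <- params$rho_y
  if (abs(rho) >= 1) stop("nonstationary: |rho_y| >= 1", call. = FALSE)
  n <- length(a$y)
  ll <- 0
  # first measurement from its stationary marginal
  ey <- mu[1] / (1 - rho)
  vy <- s2 / (1 - rho^2)
  for (j in seq_len(n)) {
    if (j > 1) {
      ey <- mu[j] + rho * ey
      vy <- s2 + rho^2 * vy
    }
    if (a$obs[j]) {
      ll <- ll + stats::dnorm(a$y[j], ey, sqrt(vy), log = TRUE)
      ey <- a$y[j]
      vy <- 0
    }
  }
  ll
}

#' Log-likelihood for discrete outcomes
#'
#' Generalized-linear-model likelihoods: Bernoulli with logit link or Poisson
#' with log link; the linear predictor uses the arm or contrast mean form and
#' optional linear trend.  `family = "normal"` is accepted as the
#' identity-link case and delegates to [loglik()].
#'
#' @inheritParams loglik
#' @return The log-likelihood (scalar).
#' @export
glm_loglik <- function(params, spec, trial) {
  if (spec$family == "normal") return(loglik(params, spec, trial))
  a <- trial_arrays(trial)
  if (!any(a$obs)) stop("trial has no non-missing outcome", call. = FALSE)
  eta <- mean_path(params, spec, a$t, a$trt)[a$obs]
  y <- a$y[a$obs]
  if (any(y != round(y))) {
    stop("discrete family requires integer outcomes", call. = FALSE)
  }
  if (spec$family == "bernoulli_logit") {
    if (any(!y %in% c(0, 1))) stop("bernoulli outcomes must be 0/1",
                                   call. = FALSE)
    sum(y * eta - log1p(exp(eta)))
  } else {
    if (any(y < 0)) stop("poisson outcomes must be non-negative",
                         call. = FALSE)
    sum(stats::dpois(y, exp(eta), log = TRUE))
  }
}
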