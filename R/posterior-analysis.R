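# Posterior decision summaries: predictive simulation, posterior predictive
# checks, responder classification and benefit/harm tables.

# parameters for one draw of a single-trial model, from a named draw vector
params_from_draw <- function(th, spec, K) {
  if (spec$parameterization == "arm") {
    single_trial_params(
      mk = unname(th[sprintf("m[%d]", seq_len(K))]),
      beta = if ("beta" %in% names(th)) th[["beta"]] else 0,
      rho_e = if (spec$autocorrelation == "ar_errors" &&
                  "rho" %in% names(th)) th[["rho"]] else 0,
      rho_y = if (spec$autocorrelation == "ar_outcomes" &&
                  "rho" %in% names(th)) th[["rho"]] else 0,
      sigma2 = if ("sigma" %in% names(th)) th[["sigma"]]^2 else 1)
  } else {
    single_trial_params(
      m = th[["m"]],
      delta = unname(th[sprintf("delta[%d]", seq(2, K))]),
      beta = if ("beta" %in% names(th)) th[["beta"]] else 0,
      rho_e = if (spec$autocorrelation == "ar_errors" &&
                  "rho" %in% names(th)) th[["rho"]] else 0,
      rho_y = if (spec$autocorrelation == "ar_outcomes" &&
                  "rho" %in% names(th)) th[["rho"]] else 0,
      sigma2 = if ("sigma" %in% names(th)) th[["sigma"]]^2 else 1)
  }
}

# simulate one outcome series at (time, treatment) given params
simulate_series <- function(params, spec, time, treatment) {
  mu <- mean_path(params, spec, time, treatment)
  n <- length(time)
  if (spec$family == "bernoulli_logit") {
    return(stats::rbinom(n, 1, stats::plogis(mu)))
  }
  if (spec$family == "poisson_log") {
    return(stats::rpois(n, exp(mu)))
  }
  s2 <- params$sigma2
  if (spec$autocorrelation == "ar_errors") {
    rho <- params$rho_e
    v <- s2 / (1 - rho^2)
    dt <- diff(time)
    if (n > 1 && all(dt == 1)) {
      # unit cadence: stationary start, then one vectorized recursion
      e1 <- stats::rnorm(1, 0, sqrt(v))
      rest <- as.numeric(stats::filter(stats::rnorm(n - 1, 0, sqrt(s2)),
                                       rho, method = "recursive",
                                       init = e1))
      e <- c(e1, rest)
    } else {
      e <- numeric(n)
      e[1] <- stats::rnorm(1, 0, sqrt(v))
      if (n > 1) {
        for (j in 2:n) {
          ph <- rho^dt[j - 1]
          e[j] <- ph * e[j - 1] + stats::rnorm(1, 0, sqrt(v * (1 - ph^2)))
        }
      }
    }
    mu + e
  } else if (spec$autocorrelation == "ar_outcomes") {
    rho <- params$rho_y
    y <- numeric(n)
    y[1] <- stats::rnorm(1, mu[1] / (1 - rho), sqrt(s2 / (1 - rho^2)))
    if (n > 1) for (j in 2:n) {
      y[j] <- stats::rnorm(1, mu[j] + rho * y[j - 1], sqrt(s2))
    }
    y
  } else {
    stats::rnorm(n, mu, sqrt(s2))
  }
}

#' Posterior predictive simulation at a new design
#'
#' For each posterior draw, simulates a new outcome series at the requested
#' times and treatments under the fitted model, mixing over parameter
#' uncertainty.  Predictive intervals are therefore wider than parameter
#' credible intervals: they add the sampling variability of new outcomes.
#'
#' @param draws An `nof1_draws` object from a single-trial fit.
#' @param new_design Data frame with columns `time` and `treatment`.
#' @param spec The [model_spec()] used for the fit (taken from the draws
#'   metadata when available).
#' @param ndraws Number of posterior draws to use (default: all).
#' @return Matrix (draws used x design rows) of simulated outcomes.
#' @export
posterior_predictive <- function(draws, new_design, spec = NULL,
                                 ndraws = NULL) {
  spec <- spec %||% draws$meta$spec
  K <- draws$meta$K %||% max(new_design$treatment)
  if (any(new_design$treatment > K | new_design$treatment < 1)) {
    stop("new design references unknown treatment code", call. = FALSE)
  }
  m <- as.matrix(draws)
  idx <- if (is.null(ndraws) || ndraws >= nrow(m)) seq_len(nrow(m)) else
    round(seq(1, nrow(m), length.out = ndraws))
  out <- matrix(NA_real_, length(idx), nrow(new_design))
  for (l in seq_along(idx)) {
    p <- params_from_draw(m[idx[l], ], spec, K)
    out[l, ] <- simulate_series(p, spec, new_design$time,
                                as.integer(new_design$treatment))
  }
  out
}

#' Posterior predictive p value
#'
#' Simulates replicated data at the trial's own design for each posterior
#' draw and returns the proportion of draws for which
#' `T(y_rep, theta) >= T(y, theta)`.  Ties count as exceedance, exactly as
#' the defining inequality reads.
#'
#' @param draws An `nof1_draws` object from a single-trial fit.
#' @param trial The observed [nof1_data] trial.
#' @param statistic Function `T(y, theta)` of an outcome vector and a named
#'   parameter draw; default the sample mean.
#' @param spec The [model_spec()] used for the fit.
#' @return Scalar p value in `[0, 1]`.
#' @export
ppc_pvalue <- function(draws, trial, statistic = function(y, theta) mean(y),
                       spec = NULL) {
  spec <- spec %||% draws$meta$spec
  df <- tibble::as_tibble(trial)
  df <- df[!is.na(df$value), ]
  K <- draws$meta$K %||% max(df$treatment)
  m <- as.matrix(draws)
  exceed <- logical(nrow(m))
  for (l in seq_len(nrow(m))) {
    th <- m[l, ]
    p <- params_from_draw(th, spec, K)
    yrep <- simulate_series(p, spec, df$time, df$treatment)
    t_rep <- statistic(yrep, th)
    t_obs <- statistic(df$value, th)
    if (!is.finite(t_rep) || !is.finite(t_obs)) {
      stop("statistic returned a nonfinite value", call. = FALSE)
    }
    exceed[l] <- t_rep >= t_obs
  }
  mean(exceed)
}

#' Classify a responder from treatment-difference draws
#'
#' A responder shows a probability of clinically meaningful improvement
#' above `p_improve` and a probability of clinically meaningful worsening
#' below `p_worse`.  With `direction = "lower"` (the default, appropriate
#' for pain interference where lower scores are better) improvement means
#' the difference is below `-mcid` and worsening that it is above `mcid`;
#' `direction = "higher"` flips both.
#'
#' @param effect_draws Numeric vector of posterior draws of a treatment
#'   difference.
#' @param mcid Minimum clinically important difference (> 0, default 3).
#' @param p_improve Required probability of improvement (default 0.5).
#' @param p_worse Tolerated probability of worsening (default 0.1).
#' @param direction `"lower"` or `"higher"`: which direction is beneficial.
#' @param comparison Label for the comparison.
#' @param level Credible-interval level.
#' @return One-row tibble: `comparison`, `median`, `lower`, `upper`,
#'   `p_improvement`, `p_worsening`, `responder`.
#' @export
classify_responder <- function(effect_draws, mcid = 3, p_improve = 0.5,
                               p_worse = 0.1,
                               direction = c("lower", "higher"),
                               comparison = "effect", level = 0.95) {
  direction <- match.arg(direction)
  if (length(effect_draws) == 0) stop("no draws supplied", call. = FALSE)
  stopifnot(mcid > 0)
  d <- if (direction == "lower") effect_draws else -effect_draws
  pi_ <- mean(d < -mcid)
  pw <- mean(d > mcid)
  a <- (1 - level) / 2
  q <- stats::quantile(effect_draws, c(a, 0.5, 1 - a), names = FALSE)
  tibble::tibble(comparison = comparison, median = q[2], lower = q[1],
                 upper = q[3], p_improvement = pi_, p_worsening = pw,
                 responder = pi_ > p_improve && pw < p_worse)
}

# per-draw difference for a comparison c(k1, k2) from whatever effect
# columns the draws carry (arm means, single-trial contrasts, or
# hyperparameter effect means)
comparison_draws <- function(draws, k1, k2) {
  m <- as.matrix(draws)
  cn <- colnames(m)
  col_of <- function(k) {
    if (sprintf("m[%d]", k) %in% cn) return(m[, sprintf("m[%d]", k)])
    if (k == 1) return(rep(0, nrow(m)))
    if (sprintf("delta[%d]", k) %in% cn) return(m[, sprintf("delta[%d]", k)])
    if (sprintf("d[%d]", k) %in% cn) return(m[, sprintf("d[%d]", k)])
    if (sprintf("d0[%d]", k) %in% cn) return(m[, sprintf("d0[%d]", k)])
    stop("no effect column found for treatment ", k, call. = FALSE)
  }
  col_of(k1) - col_of(k2)
}

#' Benefit/harm decision table
#'
#' One row per treatment comparison with the posterior median difference,
#' central credible interval, and the posterior probability that the
#' difference is below zero (benefit when lower is better), shaped like a
#' published comparison table (Median, 95%CrI, Pr<0).
#'
#' @param draws An `nof1_draws` object.
#' @param comparisons Named list of length-2 integer vectors `c(k1, k2)`;
#'   each row reports the difference `effect(k1) - effect(k2)`.
#' @param level Credible-interval level (default 0.95).
#' @param mcid,p_improve,p_worse,direction Passed to
#'   [classify_responder()] for the responder flag.
#' @return Tibble with columns `comparison`, `median`, `lower`, `upper`,
#'   `pr_less_0`, `p_improvement`, `p_worsening`, `responder`.
#' @export
benefit_harm_table <- function(draws, comparisons, level = 0.95, mcid = 3,
                               p_improve = 0.5, p_worse = 0.1,
                               direction = "lower") {
  stopifnot(length(comparisons) > 0, !is.null(names(comparisons)))
  purrr::imap(comparisons, function(ks, nm) {
    d <- comparison_draws(draws, ks[1], ks[2])
    row <- classify_responder(d, mcid = mcid, p_improve = p_improve,
                              p_worse = p_worse, direction = direction,
                              comparison = nm, level = level)
    row$pr_less_0 <- mean(d < 0)
    row[, c("comparison", "median", "lower", "upper", "pr_less_0",
            "p_improvement", "p_worsening", "responder")]
  }) |> dplyr::bind_rows()
}
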