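# Missing-outcome machinery: exact AR(1) conditional draws for MAR slots,
# completion-stratum-specific multiple imputation for informative dropout,
# and Rubin's-rules pooling.

# conditional moments of one missing value given nearest filled neighbours
# under the stationary AR(1)-error model.  phiL/phiR are rho^lag; rL/rR the
# neighbour residuals (NA if that side has no neighbour); v the stationary
# variance.
ar1_conditional <- function(mu, v, rho, lagL, rL, lagR, rR) {
  phiL <- if (is.na(lagL)) NA_real_ else rho^lagL
  phiR <- if (is.na(lagR)) NA_real_ else rho^lagR
  if (!is.na(phiL) && !is.na(phiR)) {
    den <- 1 - phiL^2 * phiR^2
    a <- phiL * (1 - phiR^2) / den
    b <- phiR * (1 - phiL^2) / den
    list(mean = mu + a * rL + b * rR,
         var = v * (1 - phiL^2) * (1 - phiR^2) / den)
  } else if (!is.na(phiL)) {
    list(mean = mu + phiL * rL, var = v * (1 - phiL^2))
  } else if (!is.na(phiR)) {
    list(mean = mu + phiR * rR, var = v * (1 - phiR^2))
  } else {
    list(mean = mu, var = v)
  }
}

#' Conditional moments of missing outcomes given the observed ones
#'
#' For every missing-value row, the exact conditional mean and variance of
#' that outcome given the *observed* outcomes and the supplied parameters,
#' using the Markov property of the stationary AR(1)-error model (nearest
#' observed neighbour on each side, lag-aware moments).
#'
#' @inheritParams impute_mar_draw
#' @return Tibble with columns `id`, `time`, `cond_mean`, `cond_var`.
#' @export
mar_conditional_moments <- function(trial, params, spec) {
  stopifnot(spec$family == "normal",
            spec$autocorrelation %in% c("none", "ar_errors"))
  df <- tibble::as_tibble(trial)
  out <- list()
  for (pid in unique(df$id)) {
    d <- df[df$id == pid, ]
    p <- if (inherits(params, "nof1_params")) params else params[[pid]]
    mu <- mean_path(p, spec, d$time, d$treatment,
                    if ("z_carry" %in% names(d)) d$z_carry,
                    if ("carry_from" %in% names(d)) d$carry_from)
    rho <- if (spec$autocorrelation == "ar_errors") p$rho_e else 0
    v <- p$sigma2 / (1 - rho^2)
    obs <- which(!is.na(d$value))
    for (j in which(is.na(d$value))) {
      left <- obs[obs < j]
      left <- if (length(left)) max(left) else NA_integer_
      right <- obs[obs > j]
      right <- if (length(right)) min(right) else NA_integer_
      cond <- ar1_conditional(
        mu[j], v, rho,
        if (is.na(left)) NA_real_ else d$time[j] - d$time[left],
        if (is.na(left)) NA_real_ else d$value[left] - mu[left],
        if (is.na(right)) NA_real_ else d$time[right] - d$time[j],
        if (is.na(right)) NA_real_ else d$value[right] - mu[right])
      out[[length(out) + 1]] <- tibble::tibble(
        id = pid, time = d$time[j], cond_mean = cond$mean,
        cond_var = cond$var)
    }
  }
  dplyr::bind_rows(out)
}

#' Draw missing outcomes from their exact conditional distribution
#'
#' Fills every missing outcome row with a draw from its conditional normal
#' distribution given the observed outcomes and the supplied parameters.
#' Under AR(1) errors the process is Markov, so each missing value is
#' conditioned on its nearest filled neighbour on each side with lag-aware
#' moments; consecutive missing values are drawn left to right so the joint
#' draw is exact.  Without autocorrelation the draws are independent
#' `N(M_j, sigma^2)`.  Draws are truncated to the declared outcome bounds
#' (truncations counted in the `truncations` attribute).  Observed values
#' are never altered.
#'
#' @param trial An [nof1_data] tibble (one or more individuals) whose
#'   missing-value rows are the slots to fill.
#' @param params A [single_trial_params()] object, or a named list of one
#'   per individual id.
#' @param spec A [model_spec()] with normal family and autocorrelation
#'   `"none"` or `"ar_errors"`.
#' @return The trial tibble with missing values replaced by draws; imputed
#'   rows are flagged in a logical `imputed` column.
#' @export
impute_mar_draw <- function(trial, params, spec) {
  stopifnot(spec$family == "normal",
            spec$autocorrelation %in% c("none", "ar_errors"))
  df <- tibble::as_tibble(trial)
  bl <- bounds_for(df, attr(trial, "bounds"))
  df$imputed <- is.na(df$value)
  truncations <- 0L
  for (pid in unique(df$id)) {
    rows <- which(df$id == pid)
    d <- df[rows, ]
    p <- if (inherits(params, "nof1_params")) params else params[[pid]]
    if (is.null(p)) stop("no parameters supplied for individual ", pid,
                         call. = FALSE)
    mu <- mean_path(p, spec, d$time, d$treatment,
                    if ("z_carry" %in% names(d)) d$z_carry,
                    if ("carry_from" %in% names(d)) d$carry_from)
    rho <- if (spec$autocorrelation == "ar_errors") p$rho_e else 0
    v <- p$sigma2 / (1 - rho^2)
    y <- d$value
    filled <- !is.na(y)
    for (j in which(!filled)) {
      left <- which(filled[seq_len(j - 1)])
      left <- if (length(left)) max(left) else NA_integer_
      right_candidates <- which(!is.na(d$value)) # observed only, to the right
      right <- right_candidates[right_candidates > j]
      right <- if (length(right)) min(right) else NA_integer_
      cond <- ar1_conditional(
        mu[j], v, rho,
        if (is.na(left)) NA_real_ else d$time[j] - d$time[left],
        if (is.na(left)) NA_real_ else y[left] - mu[left],
        if (is.na(right)) NA_real_ else d$time[right] - d$time[j],
        if (is.na(right)) NA_real_ else y[right] - mu[right])
      lo <- bl$lower[rows[j]]
      hi <- bl$upper[rows[j]]
      sd <- sqrt(cond$var)
      pl <- stats::pnorm(lo, cond$mean, sd)
      pu <- stats::pnorm(hi, cond$mean, sd)
      draw <- stats::qnorm(pl + stats::runif(1) * (pu - pl), cond$mean, sd)
      raw <- stats::rnorm(1, cond$mean, sd) # for truncation accounting
      if (raw < lo || raw > hi) truncations <- truncations + 1L
      y[j] <- min(max(draw, lo), hi)
      filled[j] <- TRUE
    }
    df$value[rows] <- y
  }
  out <- if (inherits(trial, "nof1_data")) reclass_nof1(df, trial) else df
  attr(out, "truncations") <- truncations
  out
}

#' Planned PRODUCE-like design template
#'
#' Two baseline weeks of usual diet followed by `n_periods` experimental
#' periods of `period_weeks` weeks with weekly measurements; the first
#' measurement of each experimental period is the washout slot.
#'
#' @param baseline_weeks,n_periods,period_weeks Design dimensions.
#' @return A list of class `nof1_design`.
#' @export
produce_design <- function(baseline_weeks = 2L, n_periods = 4L,
                           period_weeks = 8L) {
  structure(list(baseline_weeks = as.integer(baseline_weeks),
                 n_periods = as.integer(n_periods),
                 period_weeks = as.integer(period_weeks)),
            class = "nof1_design")
}

period_times <- function(design, p) {
  if (p == 0) return(seq_len(design$baseline_weeks) - 1)
  start <- design$baseline_weeks + (p - 1) * design$period_weeks
  start + seq_len(design$period_weeks) - 1
}

# planned treatment for each period, inferred from observed periods or a
# `sequence` column (two experimental diets: codes 2 and 3 alternate)
planned_treatments <- function(d, design) {
  trt <- rep(NA_integer_, design$n_periods)
  for (p in seq_len(design$n_periods)) {
    tp <- d$treatment[d$period == p]
    if (length(tp)) trt[p] <- tp[1]
  }
  if ("sequence" %in% names(d) && !all(is.na(d$sequence))) {
    seq_lab <- d$sequence[!is.na(d$sequence)][1]
    map <- c(A = 2L, B = 3L)
    lab <- strsplit(seq_lab, "")[[1]]
    if (all(lab %in% names(map)) && length(lab) >= design$n_periods) {
      planned <- map[lab[seq_len(design$n_periods)]]
      trt[is.na(trt)] <- planned[is.na(trt)]
    }
  }
  for (p in which(is.na(trt))) {
    if (p > 2 && !is.na(trt[p - 2])) trt[p] <- trt[p - 2]
    else if (p > 1 && !is.na(trt[p - 1])) trt[p] <- 5L - trt[p - 1]
    else if (p < design$n_periods && !is.na(trt[p + 1])) {
      trt[p] <- 5L - trt[p + 1]
    }
  }
  if (anyNA(trt)) stop("cannot infer planned treatments; supply a ",
                       "`sequence` column", call. = FALSE)
  trt
}

# add missing-value rows until minimum-measurement rules are met
expand_to_rules <- function(data, rules, design) {
  df <- tibble::as_tibble(data)
  extra <- list()
  for (pid in unique(df$id)) {
    d <- df[df$id == pid, ]
    trt <- planned_treatments(d, design)
    rep_lab <- if ("reporter" %in% names(d)) d$reporter[1] else NULL
    seq_lab <- if ("sequence" %in% names(d)) d$sequence[1] else NULL
    for (p in 0:design$n_periods) {
      need <- if (p == 0) rules$min_baseline else rules$min_period
      have <- sum(d$period == p)
      if (have >= need) next
      # candidate weekly slots; experimental periods skip the washout week
      cand <- period_times(design, p)
      if (p > 0 && length(cand) > 1) cand <- cand[-1]
      cand <- setdiff(cand, d$time)
      take <- utils::head(cand, need - have)
      if (length(take) < need - have) {
        stop("cannot satisfy minimum-measurement rule for individual ", pid,
             ", period ", p, call. = FALSE)
      }
      if (length(take)) {
        row <- tibble::tibble(id = pid, time = take, period = as.integer(p),
                              treatment = if (p == 0) 1L else trt[p],
                              value = NA_real_)
        if (!is.null(rep_lab)) row$reporter <- rep_lab
        if (!is.null(seq_lab)) row$sequence <- seq_lab
        extra[[length(extra) + 1]] <- row
      }
    }
  }
  if (length(extra)) {
    df <- dplyr::bind_rows(df, dplyr::bind_rows(extra)) |>
      dplyr::arrange(.data$id, .data$time)
  }
  if (inherits(data, "nof1_data")) {
    nof1_data(df, k = n_treatments(data), bounds = attr(data, "bounds"),
              covariates = attr(data, "covariates"))
  } else df
}

#' Completion-stratum-specific multiple imputation
#'
#' Operationalizes informative (missing-not-at-random) dropout by
#' stratifying on completion behaviour: full completers, early completers
#' and withdrawals each get their own multilevel model fit on their observed
#' data alone, and missing values for individuals in a stratum are imputed
#' from that stratum's posterior.  Missing rows are first expanded so every
#' individual meets the minimum-measurement rules (default: at least one
#' baseline measurement and at least six per experimental period); then `M`
#' completed datasets are drawn using `M` evenly spaced posterior draws.
#'
#' @param data An [nof1_data] tibble with all individuals.
#' @param M Number of imputations (default 5).
#' @param rules List with `min_baseline` and `min_period`.
#' @param design A [produce_design()] template.
#' @param spec First-level [model_spec()]; default arm-free contrast model
#'   with AR(1) errors and no trend.
#' @param level Second-level [level_spec()]; default the stratified
#'   meta-analysis configuration (fixed intercepts, random effects, common
#'   autocorrelation, common residual variance).
#' @param config [sampler_config()] for the stratum fits.
#' @return An object of class `nof1_imputation`: list with `completed`
#'   (list of M [nof1_data] tibbles), `strata`, `M`, `truncations`.
#' @export
impute_mnar_by_group <- function(data, M = 5L,
                                 rules = list(min_baseline = 1L,
                                              min_period = 6L),
                                 design = produce_design(),
                                 spec = model_spec("contrast",
                                                   autocorrelation =
                                                     "ar_errors"),
                                 level = level_spec(intercepts = "fixed",
                                                    effects = "random",
                                                    correlations = "common",
                                                    variances = "common"),
                                 config = sampler_config(chains = 2,
                                                         warmup = 400,
                                                         draws = 400)) {
  stopifnot(M >= 1)
  strata <- classify_completion(data, design$n_periods)
  full <- expand_to_rules(data, rules, design)
  df <- tibble::as_tibble(full)
  completed <- purrr::map(seq_len(M), function(m) df)
  truncations <- 0L
  for (st in unique(strata$stratum)) {
    ids <- strata$id[strata$stratum == st]
    sub_obs <- df[df$id %in% ids & !is.na(df$value), ]
    if (nrow(sub_obs) == 0) {
      stop("stratum with no usable data: ", st, call. = FALSE)
    }
    sub_obs_d <- nof1_data(sub_obs, k = n_treatments(data),
                           bounds = attr(data, "bounds"))
    model <- assemble_multilevel(sub_obs_d, spec, level,
                                 default_priors(spec, stratum_bounds(data)))
    draws <- sample_posterior(model, config)
    dm <- as.matrix(draws)
    pick <- round(seq(1, nrow(dm), length.out = M + 2))[2:(M + 1)]
    for (m in seq_len(M)) {
      th <- dm[pick[m], ]
      par_list <- stats::setNames(purrr::map(ids, function(pid) {
        dpos <- sprintf("delta[%s,%d]", pid, 2:n_treatments(data))
        single_trial_params(
          m = th[[sprintf("mu[%s]", pid)]],
          delta = unname(th[dpos]),
          rho_e = if ("rho" %in% names(th)) th[["rho"]] else 0,
          sigma2 = th[["sigma"]]^2)
      }), ids)
      sub_all <- completed[[m]][completed[[m]]$id %in% ids, ]
      sub_all_d <- nof1_data(sub_all, k = n_treatments(data),
                             bounds = attr(data, "bounds"))
      imp_spec <- spec
      filled <- impute_mar_draw(sub_all_d, par_list, imp_spec)
      truncations <- truncations + attr(filled, "truncations")
      completed[[m]]$value[completed[[m]]$id %in% ids] <- filled$value
    }
  }
  completed <- purrr::map(completed, function(d) {
    nof1_data(d, k = n_treatments(data), bounds = attr(data, "bounds"),
              covariates = attr(data, "covariates"))
  })
  structure(list(completed = completed, strata = strata, M = M,
                 truncations = truncations),
            class = "nof1_imputation")
}

# a single c(lower, upper) for prior construction: widest declared range
stratum_bounds <- function(data) {
  b <- attr(data, "bounds")
  if (is.null(b)) return(NULL)
  if (is.numeric(b)) return(b)
  c(min(vapply(b, `[`, numeric(1), 1)), max(vapply(b, `[`, numeric(1), 2)))
}

#' Pool estimates across multiple imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance =
#' mean within-imputation variance plus `(1 + 1/M)` times the
#' between-imputation variance.  The interval uses a t reference
#' distribution with the standard small-M degrees of freedom
#' `(M - 1) * (1 + Ubar / ((1 + 1/M) B))^2` (normal when the
#' between-imputation variance is zero).
#'
#' @param estimates Numeric vector of M per-imputation estimates.
#' @param variances Numeric vector of M per-imputation variances (>= 0).
#' @param level Interval level (default 0.95).
#' @return Tibble with `estimate`, `total_variance`, `lower`, `upper`,
#'   `df`, `M`.
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  M <- length(estimates)
  if (M == 0) stop("no estimates to pool", call. = FALSE)
  stopifnot(length(variances) == M, all(variances >= 0))
  qbar <- mean(estimates)
  ubar <- mean(variances)
  B <- if (M > 1) stats::var(estimates) else 0
  total <- ubar + (1 + 1 / M) * B
  df <- if (B > 0) (M - 1) * (1 + ubar / ((1 + 1 / M) * B))^2 else Inf
  q <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df) else
    stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(estimate = qbar, total_variance = total,
                 lower = qbar - q * sqrt(total),
                 upper = qbar + q * sqrt(total), df = df, M = M)
}

#' Fit each completed dataset and pool one parameter
#'
#' Convenience wrapper for the combined-analysis step: fits the multilevel
#' model to every completed dataset from [impute_mnar_by_group()], extracts
#' the posterior median and variance of one parameter, and pools them by
#' [rubin_pool()].
#'
#' @param imputation An `nof1_imputation` object.
#' @param spec,level,config Model, level and sampler settings for the
#'   per-dataset fits.
#' @param parameter Parameter name to pool (default `"d[2]"`).
#' @param priors Priors for the fits.
#' @param level_ci Interval level.
#' @return List with `per_imputation` (tibble) and `pooled` (tibble).
#' @export
fit_imputed <- function(imputation, spec, level, config,
                        parameter = "d[2]", priors = NULL,
                        level_ci = 0.95) {
  fits <- purrr::map(imputation$completed, function(d) {
    pri <- if (is.null(priors)) default_priors(spec, stratum_bounds(d)) else
      priors
    model <- assemble_multilevel(d, spec, level, pri)
    draws <- sample_posterior(model, config)
    m <- as.matrix(draws)[, parameter]
    c(est = stats::median(m), var = stats::var(m))
  })
  per <- dplyr::bind_rows(purrr::map(fits, ~ tibble::tibble(
    estimate = .x[["est"]], variance = .x[["var"]])), .id = "imputation")
  list(per_imputation = per,
       pooled = rubin_pool(per$estimate, per$variance, level_ci))
}
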