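# Model assembly: turn trial data + specs into an mcmc_model (parameter
# table, log-density terms, parameter -> term dependency map).

# fast normal/AR(1) likelihood core on pre-extracted arrays.
# r: residuals (observed order), dt: time gaps between successive residuals
ll_core <- function(r, rho, s2, dt, mode) {
  if (mode == "none") {
    return(sum(stats::dnorm(r, 0, sqrt(s2), log = TRUE)))
  }
  v <- s2 / (1 - rho^2)
  if (mode == "ar_product") {
    return(sum(stats::dnorm(r, 0, sqrt(v), log = TRUE)))
  }
  n <- length(r)
  if (n == 1) return(stats::dnorm(r, 0, sqrt(v), log = TRUE))
  rho_dt <- rho^dt
  stats::dnorm(r[1], 0, sqrt(v), log = TRUE) +
    sum(stats::dnorm(r[-1], rho_dt * r[-n], sqrt(v * (1 - rho_dt^2)),
                     log = TRUE))
}

# lagged-outcome model: forward filter marginalizing missing rows
ll_ar_outcomes <- function(y, mu, obs, rho, s2) {
  n <- length(y)
  ll <- 0
  ey <- mu[1] / (1 - rho)
  vy <- s2 / (1 - rho^2)
  for (j in seq_len(n)) {
    if (j > 1) {
      ey <- mu[j] + rho * ey
      vy <- s2 + rho^2 * vy
    }
    if (obs[j]) {
      ll <- ll + stats::dnorm(y[j], ey, sqrt(vy), log = TRUE)
      ey <- y[j]
      vy <- 0
    }
  }
  ll
}

# sd with a floor, safe for length-1 input
safe_sd <- function(x, floor = 0.2) {
  s <- stats::sd(x)
  if (!is.finite(s)) floor else max(s, floor)
}

clamp <- function(x, lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) return(x)
  pad <- if (is.finite(lo) && is.finite(hi)) 1e-6 * max(1, hi - lo) else 1e-6
  lo2 <- if (is.finite(lo)) lo + pad else -Inf
  hi2 <- if (is.finite(hi)) hi - pad else Inf
  pmin(pmax(x, lo2), hi2)
}

#' Assemble a single-trial posterior for the sampler
#'
#' Builds an [mcmc_model()] for one individual's trial under a
#' [model_spec()] and priors.  Missing outcomes can be treated as model
#' parameters (`impute_missing = TRUE`, normal family only): each missing
#' slot becomes a parameter with support equal to the outcome bounds, drawn
#' from its exact conditional inside the sampler.
#'
#' @param trial An [nof1_data] tibble containing exactly one individual.
#' @param spec A [model_spec()].
#' @param priors A prior set from [default_priors()].
#' @param impute_missing Treat missing outcome rows as parameters?
#' @return An `nof1_model` ready for [sample_posterior()].
#' @export
assemble_single_trial <- function(trial, spec,
                                  priors = default_priors(spec),
                                  impute_missing = FALSE) {
  df <- tibble::as_tibble(trial)
  if (dplyr::n_distinct(df$id) != 1) {
    stop("assemble_single_trial expects exactly one individual", call. = FALSE)
  }
  K <- if (inherits(trial, "nof1_data")) n_treatments(trial) else
    max(df$treatment)
  a <- trial_arrays(trial)
  if (!any(a$obs)) stop("trial has no non-missing outcome", call. = FALSE)
  if (impute_missing && spec$family != "normal") {
    stop("impute_missing requires the normal family", call. = FALSE)
  }
  tc <- if (spec$trend == "linear") a$t - mean(a$t[a$obs]) else a$t

  ybar <- mean(a$y[a$obs])
  ysd <- safe_sd(a$y[a$obs], 0.1)
  if (!is.finite(ysd)) ysd <- 1

  pars <- list()
  prior_of <- list()
  add <- function(name, type, transform, lower, upper, init, prior) {
    pars[[length(pars) + 1]] <<- data.frame(
      name = name, type = type, transform = transform,
      lower = lower, upper = upper, init = init)
    prior_of[[name]] <<- prior
  }
  glm_fam <- spec$family != "normal"
  mean_type <- if (glm_fam) "rw" else "gauss"

  if (spec$parameterization == "arm") {
    for (k in seq_len(K)) {
      yk <- a$y[a$obs & a$trt == k]
      init <- if (length(yk)) mean(yk) else ybar
      sup <- prior_support(priors$mean)
      add(sprintf("m[%d]", k), mean_type, "identity", sup[1], sup[2],
          clamp(init, sup[1], sup[2]), priors$mean)
    }
  } else {
    sup <- prior_support(priors$mean)
    y1 <- a$y[a$obs & a$trt == 1L]
    add("m", mean_type, "identity", sup[1], sup[2],
        clamp(if (length(y1)) mean(y1) else ybar, sup[1], sup[2]),
        priors$mean)
    supd <- prior_support(priors$contrast)
    for (k in 2:K) {
      yk <- a$y[a$obs & a$trt == k]
      init <- if (length(yk) && length(y1)) mean(yk) - mean(y1) else 0
      add(sprintf("delta[%d]", k), mean_type, "identity", supd[1], supd[2],
          clamp(init, supd[1], supd[2]), priors$contrast)
    }
  }
  if (spec$trend == "linear") {
    sup <- prior_support(priors$beta)
    add("beta", mean_type, "identity", sup[1], sup[2], 0, priors$beta)
  }
  if (spec$autocorrelation != "none") {
    sup <- prior_support(priors$rho)
    add("rho", "rw", "fisherz", max(-1, sup[1]), min(1, sup[2]), 0,
        priors$rho)
  }
  if (!glm_fam) {
    sup <- prior_support(priors$sigma)
    add("sigma", "rw", "log", max(0, sup[1]), sup[2],
        clamp(ysd, max(0, sup[1]), sup[2]), priors$sigma)
  }
  mis_rows <- integer(0)
  if (impute_missing && any(!a$obs)) {
    mis_rows <- which(!a$obs)
    bl <- bounds_for(df, attr(trial, "bounds"))
    for (r in mis_rows) {
      add(sprintf("y_mis[%d]", r), "gauss", "identity",
          bl$lower[r], bl$upper[r], clamp(ybar, bl$lower[r], bl$upper[r]),
          NULL)
    }
  }
  pars <- do.call(rbind, pars)
  pp <- function(nm) match(nm, pars$name)

  # resolved positions
  pos <- list(
    m = if (spec$parameterization == "arm") pp(sprintf("m[%d]", 1:K)) else
      pp("m"),
    delta = if (spec$parameterization == "contrast") pp(sprintf("delta[%d]",
                                                                2:K)),
    beta = if (spec$trend == "linear") pp("beta"),
    rho = if (spec$autocorrelation != "none") pp("rho"),
    sigma = if (!glm_fam) pp("sigma"),
    y_mis = if (length(mis_rows)) pp(sprintf("y_mis[%d]", mis_rows))
  )

  arm <- spec$parameterization == "arm"
  has_carry <- spec$carryover == "half_life" && !is.null(a$z_carry)
  carry_from <- if (has_carry) ifelse(is.na(a$carry_from), 1L, a$carry_from)
  mode <- switch(spec$autocorrelation,
                 none = "none",
                 ar_errors = if (spec$likelihood_mode == "paper_product")
                   "ar_product" else "ar_exact",
                 ar_outcomes = "ar_outcomes")

  use_all <- impute_missing && length(mis_rows) > 0
  sel <- if (use_all || mode == "ar_outcomes") seq_along(a$y) else which(a$obs)
  dt <- diff(a$t[sel])
  obs_sel <- a$obs[sel]

  mean_at <- function(state, rows) {
    if (arm) {
      mk <- state[pos$m]
      dfull <- mk - mk[1]
      mu <- mk[a$trt[rows]]
    } else {
      dfull <- c(0, state[pos$delta])
      mu <- state[pos$m[1]] + dfull[a$trt[rows]]
    }
    if (!is.null(pos$beta)) mu <- mu + state[pos$beta] * tc[rows]
    if (has_carry) {
      mu <- mu + ifelse(carry_from[rows] > 1L, dfull[carry_from[rows]], 0) *
        a$z_carry[rows]
    }
    mu
  }

  lik <- if (glm_fam) {
    yobs <- a$y[a$obs]
    obs_rows <- which(a$obs)
    if (spec$family == "bernoulli_logit") {
      function(state) {
        eta <- mean_at(state, obs_rows)
        sum(yobs * eta - log1p(exp(eta)))
      }
    } else {
      function(state) {
        eta <- mean_at(state, obs_rows)
        sum(stats::dpois(yobs, exp(eta), log = TRUE))
      }
    }
  } else if (mode == "ar_outcomes") {
    function(state) {
      y <- a$y
      if (use_all) y[mis_rows] <- state[pos$y_mis]
      o <- if (use_all) rep(TRUE, length(y)) else a$obs
      ll_ar_outcomes(y, mean_at(state, seq_along(y)), o,
                     state[pos$rho], state[pos$sigma]^2)
    }
  } else {
    function(state) {
      y <- a$y[sel]
      if (use_all) y[match(mis_rows, sel)] <- state[pos$y_mis]
      r <- y - mean_at(state, sel)
      rho <- if (is.null(pos$rho)) 0 else state[pos$rho]
      ll_core(r, rho, state[pos$sigma]^2, dt, mode)
    }
  }

  terms <- list(lik)
  par_terms <- stats::setNames(vector("list", nrow(pars)), pars$name)
  for (nm in pars$name) par_terms[[nm]] <- 1L
  for (nm in pars$name) {
    pr <- prior_of[[nm]]
    if (is.null(pr)) next
    j <- pp(nm)
    terms[[length(terms) + 1]] <- local({
      pr0 <- pr; j0 <- j
      function(state) prior_logdens(pr0, state[j0])
    })
    par_terms[[nm]] <- c(par_terms[[nm]], length(terms))
  }
  m <- mcmc_model(pars, terms, par_terms)
  m$meta <- list(kind = "single", spec = spec, K = K, pos = pos,
                 mis_rows = mis_rows, id = df$id[1])
  m
}

#' Evaluate a model's full log density
#'
#' Sums all log-density terms of an assembled model at a named parameter
#' vector (useful for checking model composition).
#'
#' @param model An `nof1_model`.
#' @param state Named numeric vector covering all parameters.
#' @return Scalar log density.
#' @export
model_log_density <- function(model, state) {
  j <- match(model$pars$name, names(state))
  if (anyNA(j)) stop("state missing parameter(s): ",
                     paste(model$pars$name[is.na(j)], collapse = ", "),
                     call. = FALSE)
  s <- unname(state[j])
  sum(vapply(model$terms, function(f) f(s), numeric(1)))
}

#' Assemble a multilevel (meta-analysis) posterior
#'
#' Ties per-individual first-level models (contrast parameterization,
#' Eq-style mean `mu_i + delta_ik + beta_i t`) together through the
#' second-level structure declared in a [level_spec()]: common parameters
#' appear once, fixed parameters once per individual with independent
#' priors, and random parameters get normal second-level distributions with
#' estimated hyperparameters (means, variances, and optionally the
#' structured intercept-effect covariance with its 0.5 contrast
#' correlation).  Autocorrelation random effects are modeled on the
#' Fisher-z scale.  Only observed outcomes enter the likelihood.
#'
#' @param data An [nof1_data] tibble with one or more individuals.
#' @param spec A [model_spec()] (contrast parameterization).
#' @param level A [level_spec()].
#' @param priors Priors from [default_priors()].
#' @return An `nof1_model` with a `meta` element describing the layout.
#' @export
assemble_multilevel <- function(data, spec, level = level_spec(),
                                priors = default_priors(spec)) {
  if (spec$parameterization != "contrast") {
    stop("multilevel models use the contrast parameterization", call. = FALSE)
  }
  df <- tibble::as_tibble(data)
  ids <- unique(df$id)
  N <- length(ids)
  K <- if (inherits(data, "nof1_data")) n_treatments(data) else
    max(df$treatment)
  glm_fam <- spec$family != "normal"
  mean_type <- if (glm_fam) "rw" else "gauss"

  # between-individual covariates for effect-mean regression
  xcov <- NULL
  if (length(level$effect_covariates) > 0) {
    cv <- attr(data, "covariates")
    if (is.null(cv)) stop("effect_covariates requested but data has no ",
                          "covariates table", call. = FALSE)
    missing_cov <- setdiff(level$effect_covariates, names(cv))
    if (length(missing_cov) > 0) {
      stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
    cv <- cv[match(ids, cv$id), , drop = FALSE]
    if (anyNA(cv$id)) stop("covariates missing for some individuals",
                           call. = FALSE)
    xcov <- as.matrix(cv[, level$effect_covariates, drop = FALSE])
  }

  # per-individual observed arrays
  arrs <- purrr::map(ids, function(pid) {
    d <- df[df$id == pid & !is.na(df$value), ]
    if (nrow(d) == 0) stop("individual ", pid, " has no observed outcome",
                           call. = FALSE)
    tc <- if (spec$trend == "linear") d$time - mean(d$time) else d$time
    Z <- if (length(level$within_covariates) > 0) {
      as.matrix(d[, paste0("z_", level$within_covariates), drop = FALSE])
    }
    list(y = d$value, trt = d$treatment, tc = tc, dt = diff(d$time),
         z_carry = if ("z_carry" %in% names(d)) d$z_carry,
         carry_from = if ("carry_from" %in% names(d))
           ifelse(is.na(d$carry_from), 1L, as.integer(d$carry_from)),
         Z = Z)
  })
  names(arrs) <- ids

  pars <- list()
  prior_of <- list()
  add <- function(name, type, transform, lower, upper, init, prior = NULL) {
    pars[[length(pars) + 1]] <<- data.frame(
      name = name, type = type, transform = transform,
      lower = lower, upper = upper, init = init)
    prior_of[[name]] <<- prior
  }

  mu_init <- vapply(arrs, function(a) {
    y1 <- a$y[a$trt == 1L]
    if (length(y1)) mean(y1) else mean(a$y)
  }, numeric(1))
  d_init <- matrix(0, N, K - 1)
  for (i in seq_len(N)) {
    a <- arrs[[i]]
    for (k in 2:K) {
      yk <- a$y[a$trt == k]
      y1 <- a$y[a$trt == 1L]
      if (length(yk) && length(y1)) d_init[i, k - 1] <- mean(yk) - mean(y1)
    }
  }
  pooled_sd <- safe_sd(unlist(purrr::map(arrs, "y")))

  msup <- prior_support(priors$mean)
  dsup <- prior_support(priors$contrast)
  ssup <- c(max(0, prior_support(priors$sigma)[1]),
            prior_support(priors$sigma)[2])

  # --- intercepts
  if (level$intercepts == "common") {
    add("mu", mean_type, "identity", msup[1], msup[2],
        clamp(mean(mu_init), msup[1], msup[2]), priors$mean)
  } else {
    for (i in seq_len(N)) {
      add(sprintf("mu[%s]", ids[i]), mean_type, "identity", msup[1], msup[2],
          clamp(mu_init[i], msup[1], msup[2]),
          if (level$intercepts == "fixed") priors$mean)
    }
    if (level$intercepts == "random") {
      add("m", "gauss", "identity", msup[1], msup[2],
          clamp(mean(mu_init), msup[1], msup[2]), priors$mean)
      add("sigma_mu", "rw", "log", 0, ssup[2],
          clamp(safe_sd(mu_init), 0, ssup[2]), priors$sigma)
    }
  }
  # --- effects
  if (level$effects == "common") {
    for (k in 2:K) {
      add(sprintf("d[%d]", k), mean_type, "identity", dsup[1], dsup[2],
          clamp(mean(d_init[, k - 1]), dsup[1], dsup[2]), priors$contrast)
    }
  } else {
    for (i in seq_len(N)) for (k in 2:K) {
      add(sprintf("delta[%s,%d]", ids[i], k), mean_type, "identity",
          dsup[1], dsup[2], clamp(d_init[i, k - 1], dsup[1], dsup[2]),
          if (level$effects == "fixed") priors$contrast)
    }
    if (level$effects == "random") {
      if (is.null(xcov)) {
        for (k in 2:K) {
          add(sprintf("d[%d]", k), "gauss", "identity", dsup[1], dsup[2],
              clamp(mean(d_init[, k - 1]), dsup[1], dsup[2]),
              priors$contrast)
        }
      } else {
        for (k in 2:K) {
          add(sprintf("d0[%d]", k), "gauss", "identity", dsup[1], dsup[2],
              clamp(mean(d_init[, k - 1]), dsup[1], dsup[2]),
              priors$contrast)
          for (nm in colnames(xcov)) {
            add(sprintf("d_%s[%d]", nm, k), "gauss", "identity", -Inf, Inf,
                0, prior_normal(0, 1000))
          }
        }
      }
      add("sigma_delta", "rw", "log", 0, ssup[2],
          clamp(safe_sd(d_init[, 1]), 0, ssup[2]), priors$sigma)
    }
  }
  # --- trends
  if (spec$trend == "linear") {
    if (level$trends == "common") {
      add("beta", mean_type, "identity", -Inf, Inf, 0, priors$beta)
    } else {
      for (i in seq_len(N)) {
        add(sprintf("beta[%s]", ids[i]), mean_type, "identity", -Inf, Inf, 0,
            if (level$trends == "fixed") priors$beta)
      }
      if (level$trends == "random") {
        add("b", "gauss", "identity", -Inf, Inf, 0, priors$beta)
        add("sigma_beta", "rw", "log", 0, ssup[2], 0.5, priors$sigma)
      }
    }
  }
  # --- autocorrelations
  has_ar <- spec$autocorrelation != "none"
  if (has_ar) {
    rsup <- prior_support(priors$rho)
    if (level$correlations == "common") {
      add("rho", "rw", "fisherz", max(-1, rsup[1]), min(1, rsup[2]), 0,
          priors$rho)
    } else if (level$correlations == "fixed") {
      for (i in seq_len(N)) {
        add(sprintf("rho[%s]", ids[i]), "rw", "fisherz",
            max(-1, rsup[1]), min(1, rsup[2]), 0, priors$rho)
      }
    } else {
      for (i in seq_len(N)) {
        add(sprintf("ze[%s]", ids[i]), "rw", "identity", -Inf, Inf, 0)
      }
      add("ze", "gauss", "identity", -Inf, Inf, 0, prior_normal(0, 1000))
      add("sigma_ze", "rw", "log", 0, ssup[2], 0.5, priors$sigma)
    }
  }
  # --- residual scales
  if (level$variances == "common") {
    add("sigma", "rw", "log", ssup[1], ssup[2],
        clamp(pooled_sd, ssup[1], ssup[2]), priors$sigma)
  } else {
    for (i in seq_len(N)) {
      sdi <- safe_sd(arrs[[i]]$y)
      add(sprintf("sigma[%s]", ids[i]), "rw", "log", ssup[1], ssup[2],
          clamp(sdi, ssup[1], ssup[2]), priors$sigma)
    }
  }
  # --- structured covariance correlation
  correlated <- level$correlation_structure == "mu_delta_correlated"
  if (correlated) {
    add("rho_mud", "rw", "fisherz", -1, 1, 0, prior_uniform(-1, 1))
  }
  # --- within-individual covariate coefficients
  nzw <- length(level$within_covariates)
  if (nzw > 0) {
    for (nm in level$within_covariates) {
      if (level$within_treatment == "common") {
        add(sprintf("g_%s", nm), mean_type, "identity", -Inf, Inf, 0,
            prior_normal(0, 1000))
      } else {
        for (i in seq_len(N)) {
          add(sprintf("g_%s[%s]", nm, ids[i]), mean_type, "identity",
              -Inf, Inf, 0, prior_normal(0, 1000))
        }
      }
    }
  }

  pars <- do.call(rbind, pars)
  pp <- function(nm) match(nm, pars$name)

  mu_pos <- if (level$intercepts == "common") rep(pp("mu"), N) else
    pp(sprintf("mu[%s]", ids))
  delta_pos <- matrix(0L, N, K - 1)
  for (k in 2:K) {
    delta_pos[, k - 1] <- if (level$effects == "common")
      rep(pp(sprintf("d[%d]", k)), N) else
        pp(sprintf("delta[%s,%d]", ids, k))
  }
  beta_pos <- if (spec$trend != "linear") NULL else
    if (level$trends == "common") rep(pp("beta"), N) else
      pp(sprintf("beta[%s]", ids))
  rho_pos <- NULL
  rho_is_z <- FALSE
  if (has_ar) {
    if (level$correlations == "common") {
      rho_pos <- rep(pp("rho"), N)
    } else if (level$correlations == "fixed") {
      rho_pos <- pp(sprintf("rho[%s]", ids))
    } else {
      rho_pos <- pp(sprintf("ze[%s]", ids))
      rho_is_z <- TRUE
    }
  }
  sigma_pos <- if (level$variances == "common") rep(pp("sigma"), N) else
    pp(sprintf("sigma[%s]", ids))
  g_pos <- NULL
  if (nzw > 0) {
    g_pos <- matrix(0L, N, nzw)
    for (l in seq_len(nzw)) {
      nm <- level$within_covariates[l]
      g_pos[, l] <- if (level$within_treatment == "common")
        rep(pp(sprintf("g_%s", nm)), N) else
          pp(sprintf("g_%s[%s]", nm, ids))
    }
  }

  mode <- switch(spec$autocorrelation,
                 none = "none",
                 ar_errors = if (spec$likelihood_mode == "paper_product")
                   "ar_product" else "ar_exact",
                 ar_outcomes = "ar_outcomes")
  has_carry <- spec$carryover == "half_life"

  make_lik <- function(i) {
    a <- arrs[[i]]
    pm <- mu_pos[i]
    pd <- delta_pos[i, ]
    pb <- if (!is.null(beta_pos)) beta_pos[i]
    pr <- if (!is.null(rho_pos)) rho_pos[i]
    ps <- sigma_pos[i]
    pg <- if (!is.null(g_pos)) g_pos[i, ]
    carry_on <- has_carry && !is.null(a$z_carry)
    if (glm_fam) {
      fam <- spec$family
      function(state) {
        dfull <- c(0, state[pd])
        eta <- state[pm] + dfull[a$trt]
        if (!is.null(pb)) eta <- eta + state[pb] * a$tc
        if (!is.null(pg)) eta <- eta + drop(a$Z %*% state[pg])
        if (fam == "bernoulli_logit") sum(a$y * eta - log1p(exp(eta)))
        else sum(stats::dpois(a$y, exp(eta), log = TRUE))
      }
    } else {
      function(state) {
        dfull <- c(0, state[pd])
        mu <- state[pm] + dfull[a$trt]
        if (!is.null(pb)) mu <- mu + state[pb] * a$tc
        if (!is.null(pg)) mu <- mu + drop(a$Z %*% state[pg])
        if (carry_on) {
          mu <- mu + ifelse(a$carry_from > 1L, dfull[a$carry_from], 0) *
            a$z_carry
        }
        rho <- if (is.null(pr)) 0 else if (rho_is_z) tanh(state[pr]) else
          state[pr]
        if (mode == "ar_outcomes") {
          ll_ar_outcomes(a$y, mu, rep(TRUE, length(a$y)), rho, state[ps]^2)
        } else {
          ll_core(a$y - mu, rho, state[ps]^2, a$dt, mode)
        }
      }
    }
  }
  terms <- purrr::map(seq_len(N), make_lik)
  par_terms <- stats::setNames(vector("list", nrow(pars)), pars$name)
  for (nm in pars$name) par_terms[[nm]] <- integer(0)
  link <- function(nm, term_id) {
    par_terms[[nm]] <<- c(par_terms[[nm]], term_id)
  }
  for (i in seq_len(N)) {
    for (p in unique(c(mu_pos[i], delta_pos[i, ], beta_pos[i],
                       if (!is.null(rho_pos)) rho_pos[i], sigma_pos[i],
                       if (!is.null(g_pos)) g_pos[i, ]))) {
      if (!is.na(p)) link(pars$name[p], i)
    }
  }

  add_term <- function(f, involved) {
    terms[[length(terms) + 1]] <<- f
    for (nm in involved) link(nm, length(terms))
  }

  # random-effect densities
  if (level$effects == "random" && !correlated) {
    dmat_pos <- delta_pos
    sd_pos <- pp("sigma_delta")
    if (is.null(xcov)) {
      dk_pos <- pp(sprintf("d[%d]", 2:K))
      add_term(function(state) {
        s <- 0
        for (k in seq_len(K - 1)) {
          s <- s + sum(stats::dnorm(state[dmat_pos[, k]], state[dk_pos[k]],
                                    state[sd_pos], log = TRUE))
        }
        s
      }, c(pars$name[as.vector(dmat_pos)], pars$name[dk_pos],
           "sigma_delta"))
    } else {
      d0_pos <- pp(sprintf("d0[%d]", 2:K))
      dc_pos <- matrix(0L, ncol(xcov), K - 1)
      for (k in 2:K) {
        dc_pos[, k - 1] <- pp(sprintf("d_%s[%d]", colnames(xcov), k))
      }
      add_term(function(state) {
        s <- 0
        for (k in seq_len(K - 1)) {
          mk <- state[d0_pos[k]] + drop(xcov %*% state[dc_pos[, k]])
          s <- s + sum(stats::dnorm(state[dmat_pos[, k]], mk, state[sd_pos],
                                    log = TRUE))
        }
        s
      }, c(pars$name[as.vector(dmat_pos)], pars$name[d0_pos],
           pars$name[as.vector(dc_pos)], "sigma_delta"))
    }
  }
  if (level$intercepts == "random" && !correlated) {
    mp <- unique(mu_pos)
    add_term(function(state) {
      sum(stats::dnorm(state[mp], state[pp("m")], state[pp("sigma_mu")],
                       log = TRUE))
    }, c(pars$name[mp], "m", "sigma_mu"))
  }
  if (correlated) {
    mp <- mu_pos
    dmat_pos <- delta_pos
    dk_pos <- if (is.null(xcov)) pp(sprintf("d[%d]", 2:K)) else
      pp(sprintf("d0[%d]", 2:K))
    m_pos <- pp("m")
    smu_pos <- pp("sigma_mu")
    sd_pos <- pp("sigma_delta")
    rmd_pos <- pp("rho_mud")
    kc <- K - 1
    P <- matrix(0.5, kc, kc); diag(P) <- 1
    add_term(function(state) {
      S <- matrix(NA_real_, K, K)
      S[1, 1] <- state[smu_pos]^2
      S[1, -1] <- S[-1, 1] <- state[rmd_pos] * state[smu_pos] * state[sd_pos]
      S[-1, -1] <- state[sd_pos]^2 * P
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      X <- cbind(state[mp] - state[m_pos],
                 matrix(state[as.vector(dmat_pos)], N, kc) -
                   matrix(state[dk_pos], N, kc, byrow = TRUE))
      Q <- backsolve(ch, t(X), transpose = TRUE)
      -N * sum(log(diag(ch))) - 0.5 * sum(Q^2) - N * K / 2 * log(2 * pi)
    }, c(pars$name[mp], pars$name[as.vector(dmat_pos)], pars$name[dk_pos],
         "m", "sigma_mu", "sigma_delta", "rho_mud"))
  }
  if (spec$trend == "linear" && level$trends == "random") {
    bp <- unique(beta_pos)
    add_term(function(state) {
      sum(stats::dnorm(state[bp], state[pp("b")], state[pp("sigma_beta")],
                       log = TRUE))
    }, c(pars$name[bp], "b", "sigma_beta"))
  }
  if (has_ar && level$correlations == "random") {
    zp <- unique(rho_pos)
    add_term(function(state) {
      sum(stats::dnorm(state[zp], state[pp("ze")], state[pp("sigma_ze")],
                       log = TRUE))
    }, c(pars$name[zp], "ze", "sigma_ze"))
  }

  # prior terms
  for (nm in pars$name) {
    prr <- prior_of[[nm]]
    if (is.null(prr)) next
    j <- pp(nm)
    add_term(local({
      pr0 <- prr; j0 <- j
      function(state) prior_logdens(pr0, state[j0])
    }), nm)
  }

  m <- mcmc_model(pars, terms, par_terms)
  m$meta <- list(kind = "multilevel", spec = spec, level = level, K = K,
                 ids = ids, mu_pos = mu_pos, delta_pos = delta_pos,
                 beta_pos = beta_pos, rho_pos = rho_pos,
                 rho_is_z = rho_is_z, sigma_pos = sigma_pos)
  m
}
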