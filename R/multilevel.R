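#' Structured intercept-effect covariance matrix
#'
#' Covariance of the per-individual vector `(mu_i, delta_i2, ..., delta_iK)`:
#' intercept variance `sigma_mu^2`; correlation `rho_mu_delta` between the
#' intercept and every treatment effect; effect block
#' `sigma_delta^2 * P(0.5)` over the K-1 contrasts, where `P(0.5)` has unit
#' diagonal and all off-diagonals 0.5.  The 0.5 is forced by consistency:
#' with a constant treatment variance every pairwise contrast
#' `delta_ik - delta_ik'` must have the same variance, which pins the
#' correlation between contrasts at exactly 1/2.
#'
#' @param sigma_mu,sigma_delta Between-individual standard deviations (> 0).
#' @param rho_mu_delta Intercept-effect correlation.
#' @param K Number of treatments (>= 2); the matrix is K x K.
#' @return A symmetric positive-definite K x K matrix.
#' @export
#' @examples
#' build_sigma_mu_delta(1, 1, 0, K = 3)
build_sigma_mu_delta <- function(sigma_mu, sigma_delta, rho_mu_delta, K) {
  stopifnot(sigma_mu > 0, sigma_delta > 0, K >= 2,
            abs(rho_mu_delta) <= 1)
  kc <- K - 1
  P <- matrix(0.5, kc, kc)
  diag(P) <- 1
  S <- matrix(NA_real_, K, K)
  S[1, 1] <- sigma_mu^2
  S[1, -1] <- S[-1, 1] <- rho_mu_delta * sigma_mu * sigma_delta
  S[-1, -1] <- sigma_delta^2 * P
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    # with the 0.5 contrast block, PD requires rho^2 < (1 + (K-2)/2) / (K-1)
    bound <- sqrt((1 + (K - 2) * 0.5) / (K - 1))
    stop("Sigma_mu_delta not positive definite: |rho_mu_delta| must be ",
         "below ", signif(bound, 4), " for K = ", K, call. = FALSE)
  }
  S
}

#' Fisher-z transform and its inverse
#'
#' `fisher_z()` maps a correlation in (-1, 1) to the real line via the
#' inverse hyperbolic tangent, `z = 0.5 * log((1 + rho) / (1 - rho))`;
#' `inv_fisher_z()` maps back via `tanh`.  Used to give autocorrelation
#' random effects a normal second-level distribution.
#'
#' @param rho Correlation in (-1, 1).
#' @param z Real number.
#' @return Transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  atanh(rho)
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) {
  # cap at the largest double below 1 so extreme z stay strictly inside (-1,1)
  cap <- 1 - .Machine$double.eps
  pmin(pmax(tanh(z), -cap), cap)
}

#' Exponentially decaying carryover covariate
#'
#' Carryover of a treatment with half-life `half_life` into the period that
#' follows a crossover at time `t_star` is modeled by the covariate
#' `z = 2^(-(t - t_star) / half_life)`, equal to 1 at the crossover instant
#' and halving every `half_life` weeks.  With the carryover coefficient tied
#' to the treatment effect, the total effect at `t` is `delta * (1 + z)`
#' ([total_effect()]).
#'
#' @param t Measurement time (weeks); must be `>= t_star`.
#' @param t_star Crossover time (weeks).
#' @param half_life Half-life of the carried-over treatment (weeks, > 0).
#' @return Covariate value in (0, 1].
#' @export
carryover_covariate <- function(t, t_star, half_life = 1) {
  stopifnot(half_life > 0)
  if (any(t < t_star)) stop("t must be >= t_star (crossover time)",
                            call. = FALSE)
  2^(-(t - t_star) / half_life)
}

#' @rdname carryover_covariate
#' @param delta Treatment effect of the carried-over treatment.
#' @param z Carryover covariate value.
#' @export
total_effect <- function(delta, z) delta * (1 + z)

#' Attach a carryover covariate to trial data
#'
#' Adds columns `z_carry` (decay value) and `carry_from` (treatment code
#' whose effect carries over) for measurements in the period immediately
#' following a crossover out of a non-reference treatment into the
#' configured receiving treatment(s).  Also checks, per individual, that the
#' joint design matrix of treatment indicators and carryover column has full
#' rank; confounded designs (e.g. strictly alternating sequences) are
#' reported with a warning rather than silently fit.
#'
#' @param data An [nof1_data] tibble.
#' @param half_life Carryover half-life in weeks.
#' @param into Treatment codes that can receive carryover (default: the
#'   reference treatment 1, the carryover-into-placebo configuration).
#' @return `data` with `z_carry` and `carry_from` columns.
#' @export
add_carryover_covariate <- function(data, half_life = 1, into = 1L) {
  df <- tibble::as_tibble(data)
  df$z_carry <- 0
  df$carry_from <- NA_integer_
  for (pid in unique(df$id)) {
    rows <- which(df$id == pid)
    d <- df[rows, ]
    pers <- unique(d$period[order(d$time)])
    for (j in seq_along(pers)[-1]) {
      cur <- pers[j]
      prev <- pers[j - 1]
      prev_trt <- d$treatment[d$period == prev][1]
      cur_trt <- d$treatment[d$period == cur][1]
      if (prev_trt > 1L && cur_trt %in% into) {
        t_star <- min(d$time[d$period == cur])
        in_per <- d$period == cur
        df$z_carry[rows[in_per]] <-
          carryover_covariate(d$time[in_per], t_star, half_life)
        df$carry_from[rows[in_per]] <- prev_trt
      }
    }
    # identifiability: treatment indicators + carryover-effect column
    d2 <- df[rows, ]
    k <- max(df$treatment)
    X <- cbind(1, sapply(2:k, function(kk) as.numeric(d2$treatment == kk)),
               ifelse(!is.na(d2$carry_from), d2$z_carry, 0))
    if (qr(X)$rank < ncol(X)) {
      warning("carryover covariate confounded with treatment/sequence for ",
              "individual ", pid, call. = FALSE)
    }
  }
  reclass_nof1(df, data)
}

#' Second-level structure of a multilevel model
#'
#' Declares how each family of first-level parameters is treated when
#' aggregating trials: `"common"` (one shared parameter), `"fixed"`
#' (independent per-individual parameters, nuisance), or `"random"`
#' (drawn from a normal second-level distribution with estimated mean and
#' variance).  Residual variances may only be common or fixed.
#'
#' @param intercepts,effects,trends,correlations One of "common", "fixed",
#'   "random".
#' @param variances "common" or "fixed".
#' @param correlation_structure "independent" or "mu_delta_correlated"
#'   (structured covariance [build_sigma_mu_delta()]; requires random
#'   intercepts and random effects).
#' @param effect_covariates Character vector of per-individual covariate
#'   names entering the effect means as `d_k = d0_k + sum_j d_jk x_jk`.
#' @param within_covariates Character vector of per-measurement covariate
#'   column names (prefixed `z_` in the data) entering the first-level mean.
#' @param within_treatment "common" or "fixed" coefficients for the
#'   within-individual covariates.
#' @return A list of class `nof1_level_spec`.
#' @export
level_spec <- function(intercepts = c("fixed", "random", "common"),
                       effects = c("random", "common", "fixed"),
                       trends = c("random", "common", "fixed"),
                       correlations = c("common", "fixed", "random"),
                       variances = c("common", "fixed"),
                       correlation_structure = c("independent",
                                                 "mu_delta_correlated"),
                       effect_covariates = character(),
                       within_covariates = character(),
                       within_treatment = c("common", "fixed")) {
  out <- list(
    intercepts = match.arg(intercepts),
    effects = match.arg(effects),
    trends = match.arg(trends),
    correlations = match.arg(correlations),
    variances = match.arg(variances),
    correlation_structure = match.arg(correlation_structure),
    effect_covariates = effect_covariates,
    within_covariates = within_covariates,
    within_treatment = match.arg(within_treatment)
  )
  if (out$correlation_structure == "mu_delta_correlated" &&
      !(out$intercepts == "random" && out$effects == "random")) {
    stop("mu_delta_correlated requires random intercepts and random effects",
         call. = FALSE)
  }
  structure(out, class = "nof1_level_spec")
}

#' Subgroup treatment effects from covariate-adjusted hyperparameters
#'
#' For a model whose effect means are regressions
#' `d_k = d0_k + sum_j d_jk x_j`, computes the per-draw effect at two
#' covariate settings and their difference, so that [prob_event()] can give
#' e.g. the probability that improvement is larger in one subgroup.
#'
#' @param draws An `nof1_draws` object from a multilevel fit with
#'   `effect_covariates`.
#' @param setting1,setting2 Named numeric vectors of covariate values.
#' @param k Treatment code of the effect (default 2).
#' @return Tibble with per-draw columns `effect1`, `effect2`, `difference`.
#' @export
subgroup_effect <- function(draws, setting1, setting2, k = 2L) {
  m <- as.matrix(draws)
  base <- sprintf("d0[%d]", k)
  if (!base %in% colnames(m)) {
    base <- sprintf("d[%d]", k)
    if (!base %in% colnames(m)) stop("no effect mean found for k = ", k,
                                     call. = FALSE)
  }
  lincomb <- function(setting) {
    eff <- m[, base]
    for (nm in names(setting)) {
      col <- sprintf("d_%s[%d]", nm, k)
      if (!col %in% colnames(m)) stop("unknown covariate coefficient: ", nm,
                                      call. = FALSE)
      eff <- eff + m[, col] * setting[[nm]]
    }
    eff
  }
  e1 <- lincomb(setting1)
  e2 <- lincomb(setting2)
  tibble::tibble(effect1 = e1, effect2 = e2, difference = e1 - e2)
}
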