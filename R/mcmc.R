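#' Sampler configuration
#'
#' @param chains Number of chains (>= 1).
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param draws Post-warmup draws per chain (>= 1).
#' @param seed Integer seed; each chain receives a distinct deterministic
#'   sub-seed derived from it.
#' @param rhat_threshold Convergence threshold for the potential scale
#'   reduction factor (default 1.05).
#' @param step Optional named numeric vector of initial random-walk step
#'   sizes (transformed scale); adapted during warmup only.
#' @return A list of class `nof1_sampler_config`.
#' @export
sampler_config <- function(chains = 4L, warmup = 2500L, draws = 2500L,
                           seed = 1L, rhat_threshold = 1.05, step = NULL) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1, rhat_threshold >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold, step = step),
            class = "nof1_sampler_config")
}

#' Build a sampler-ready model from log-density terms
#'
#' A model is a set of scalar parameters and a log posterior density written
#' as a sum of *terms*, each a function of the full parameter vector.  Each
#' parameter lists the terms its full conditional depends on, so updates only
#' recompute what changed.  Parameters of type `"gauss"` have a Gaussian full
#' conditional (e.g. means, contrasts, random effects under normal models)
#' and are updated by an exact Gibbs draw obtained from a local quadratic fit
#' of the log density, truncated to the declared support.  Type `"rw"`
#' parameters are updated by adaptive random-walk Metropolis on a transformed
#' scale (`"log"` for scales, `"fisherz"` for correlations).
#'
#' @param pars Data frame with columns `name`, `type` ("gauss"/"rw"),
#'   `transform` ("identity"/"log"/"fisherz"), `lower`, `upper`, `init`.
#' @param terms List of functions `f(state)` returning scalar log-density
#'   contributions; `state` is the unnamed numeric parameter vector in the
#'   order of `pars$name`.
#' @param par_terms Named list mapping each parameter name to the integer
#'   indices of the terms that involve it.
#' @return A list of class `nof1_model`.
#' @export
mcmc_model <- function(pars, terms, par_terms) {
  pars <- as.data.frame(pars, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "type", "transform", "lower", "upper", "init") %in%
                  names(pars)),
            !anyDuplicated(pars$name),
            setequal(names(par_terms), pars$name))
  par_terms <- lapply(par_terms[pars$name], unique)
  structure(list(pars = pars, terms = terms, par_terms = par_terms),
            class = "nof1_model")
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1009 + chain * 7919) %% 2147483629)
}

transform_to <- function(x, tr) {
  switch(tr, identity = x, log = log(x), fisherz = atanh(x))
}
transform_from <- function(z, tr) {
  switch(tr, identity = z, log = exp(z), fisherz = tanh(z))
}
log_jacobian <- function(x, tr) {
  switch(tr, identity = 0, log = log(x), fisherz = log1p(-x^2))
}

# exact Gibbs draw for a Gaussian full conditional via local quadratic fit:
# for a quadratic log density the fitted mean/variance are exact for any h
gauss_update <- function(state, p, model, tv, lo, hi, rng_u) {
  idx <- model$par_terms[[p]]
  f <- function(x) {
    state[p] <- x
    s <- 0
    for (i in idx) s <- s + model$terms[[i]](state)
    s
  }
  x0 <- state[p]
  h <- max(abs(x0) * 0.05, 0.25)
  if (is.finite(hi)) h <- min(h, (hi - x0) / 2)
  if (is.finite(lo)) h <- min(h, (x0 - lo) / 2)
  if (h <= 0 || !is.finite(h)) h <- 1e-4
  f0 <- sum(tv[idx])
  fp <- f(x0 + h)
  fm <- f(x0 - h)
  curv <- (fp + fm - 2 * f0) / h^2
  if (!is.finite(curv) || curv >= 0) return(NULL)  # not Gaussian here
  v <- -1 / curv
  m <- x0 + v * (fp - fm) / (2 * h)
  sd <- sqrt(v)
  pl <- if (is.finite(lo)) stats::pnorm(lo, m, sd) else 0
  pu <- if (is.finite(hi)) stats::pnorm(hi, m, sd) else 1
  if (pu - pl < 1e-12) return(NULL)                # degenerate truncation
  x1 <- stats::qnorm(pl + rng_u * (pu - pl), m, sd)
  if (!is.finite(x1)) return(NULL)
  x1
}

#' Draw posterior samples by Metropolis-within-Gibbs
#'
#' Runs the componentwise sampler over a model built with [mcmc_model()]
#' (directly or via [assemble_single_trial()] / [assemble_multilevel()]).
#' Random-walk step sizes adapt toward a 44% acceptance rate during warmup
#' and are frozen afterwards, preserving detailed balance.  Chains are
#' deterministic given `config$seed`.
#'
#' @param model An `nof1_model`.
#' @param config A [sampler_config()].
#' @param init Optional named numeric vector overriding the model's initial
#'   values.
#' @return An object of class `nof1_draws`: post-warmup draws from all
#'   chains, with per-parameter acceptance rates and the configuration used.
#' @export
sample_posterior <- function(model, config = sampler_config(), init = NULL) {
  pars <- model$pars
  npar <- nrow(pars)
  pnames <- pars$name
  state0 <- pars$init
  if (!is.null(init)) {
    j <- match(names(init), pnames)
    if (anyNA(j)) stop("unknown parameter in init: ",
                       paste(names(init)[is.na(j)], collapse = ", "),
                       call. = FALSE)
    state0[j] <- unname(init)
  }
  nterm <- length(model$terms)
  tv0 <- vapply(model$terms, function(f) f(state0), numeric(1))
  if (!all(is.finite(tv0))) {
    stop("log density not finite at initial values; re-initialize ",
         "(offending term ", which(!is.finite(tv0))[1], ")", call. = FALSE)
  }
  step0 <- rep(0.25, npar)
  names(step0) <- pnames
  if (!is.null(config$step)) {
    j <- match(names(config$step), pnames)
    step0[j[!is.na(j)]] <- config$step[!is.na(j)]
  }
  is_rw <- pars$type == "rw"
  total <- config$warmup + config$draws

  chains_out <- vector("list", config$chains)
  accept_out <- matrix(NA_real_, config$chains, npar,
                       dimnames = list(NULL, pnames))
  for (ch in seq_len(config$chains)) {
    set.seed(chain_seed(config$seed, ch))
    state <- state0
    tv <- tv0
    step <- step0
    acc <- rep(0, npar)
    prop <- rep(0, npar)
    out <- matrix(NA_real_, config$draws, npar, dimnames = list(NULL, pnames))
    for (it in seq_len(total)) {
      for (p in seq_len(npar)) {
        idx <- model$par_terms[[p]]
        if (!is_rw[p]) {
          x1 <- gauss_update(state, p, model, tv, pars$lower[p],
                             pars$upper[p], stats::runif(1))
          if (!is.null(x1)) {
            state[p] <- x1
            for (i in idx) tv[i] <- model$terms[[i]](state)
            next
          }
          # fall through to a random-walk step if the conditional was not
          # usable (e.g. flat directions early in warmup)
        }
        x0 <- state[p]
        tr <- pars$transform[p]
        z1 <- transform_to(x0, tr) + step[p] * stats::rnorm(1)
        x1 <- transform_from(z1, tr)
        prop[p] <- prop[p] + 1
        ok <- x1 > pars$lower[p] && x1 < pars$upper[p] && is.finite(x1)
        if (ok) {
          state[p] <- x1
          f1 <- 0
          for (i in idx) f1 <- f1 + model$terms[[i]](state)
          if (is.nan(f1)) {
            stop("NaN log density while sampling; state: ",
                 paste(pnames, signif(state, 4), sep = "=", collapse = ", "),
                 call. = FALSE)
          }
          lr <- f1 - sum(tv[idx]) +
            log_jacobian(x1, tr) - log_jacobian(x0, tr)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            for (i in idx) tv[i] <- model$terms[[i]](state)
            acc[p] <- acc[p] + 1
          } else {
            state[p] <- x0
          }
        }
        if (it <= config$warmup) {
          a <- if (ok) min(1, exp(lr)) else 0
          step[p] <- step[p] * exp(min(0.1, 3 / sqrt(it)) * (a - 0.44))
        }
      }
      if (it > config$warmup) out[it - config$warmup, ] <- state
    }
    chains_out[[ch]] <- out
    accept_out[ch, ] <- ifelse(prop > 0, acc / pmax(prop, 1), NA_real_)
  }
  structure(list(chains = chains_out, par_names = pnames, config = config,
                 accept = accept_out, pars = pars, meta = model$meta),
            class = "nof1_draws")
}

#' @export
print.nof1_draws <- function(x, ...) {
  cat("<nof1_draws> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " draws, ", length(x$par_names),
      " parameters\n", sep = "")
  print(summarize_draws(x), ...)
  invisible(x)
}

#' Stack all chains into one draws matrix
#'
#' @param x An `nof1_draws` object.
#' @param ... Unused.
#' @return Numeric matrix (total draws x parameters).
#' @export
as.matrix.nof1_draws <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Tidy posterior draws into long format
#'
#' @inheritParams as.matrix.nof1_draws
#' @return Tibble with columns `chain`, `.draw`, `parameter`, `value`.
#' @export
as_draws_df <- function(x) {
  purrr::imap(x$chains, function(m, ch) {
    tibble::as_tibble(m) |>
      dplyr::mutate(chain = as.integer(ch), .draw = dplyr::row_number())
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(-c("chain", ".draw"), names_to = "parameter",
                        values_to = "value")
}

#' Export draws as a long-format CSV
#'
#' @inheritParams as.matrix.nof1_draws
#' @param path Output file path.
#' @export
write_draws_csv <- function(x, path) {
  readr::write_csv(as_draws_df(x), path)
  invisible(path)
}

#' Potential scale reduction factor (split-chain R-hat)
#'
#' Computes the Gelman-Rubin diagnostic per parameter.  Every chain is split
#' in half first, so a single chain yields the split-half statistic.
#' Parameters with zero variance in all chains are reported as 1 with a
#' degenerate-parameter warning.
#'
#' @param draws An `nof1_draws` object.
#' @return Tibble with columns `parameter`, `rhat`, `converged`.
#' @export
gelman_rubin <- function(draws) {
  halves <- purrr::map(draws$chains, function(m) {
    n <- nrow(m)
    h <- n %/% 2
    list(m[seq_len(h), , drop = FALSE],
         m[(n - h + 1):n, , drop = FALSE])
  }) |> purrr::flatten()
  rhat <- vapply(seq_along(draws$par_names), function(j) {
    xs <- purrr::map(halves, ~ .x[, j])
    n <- length(xs[[1]])
    w <- mean(vapply(xs, stats::var, numeric(1)))
    b <- n * stats::var(vapply(xs, mean, numeric(1)))
    if (!is.finite(w) || w == 0) {
      if (b > 0) return(Inf)  # stuck chains at different levels
      warning("degenerate parameter (zero variance): ",
              draws$par_names[j], call. = FALSE)
      return(1)
    }
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
  tibble::tibble(parameter = draws$par_names, rhat = rhat,
                 converged = rhat <= draws$config$rhat_threshold)
}

# effective sample size via Geyer's initial positive sequence, per parameter
ess_basic <- function(chains_j) {
  n <- length(chains_j[[1]])
  m <- length(chains_j)
  w <- mean(vapply(chains_j, stats::var, numeric(1)))
  if (!is.finite(w) || w == 0) return(n * m)
  rho_sum <- 0
  max_lag <- min(n - 2, 200)
  ac <- sapply(chains_j, function(x) {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
    a
  })
  ac <- rowMeans(as.matrix(ac))
  if (length(ac) < 2) return(n * m)
  for (l in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[l] + ac[l + 1]
    if (is.na(pair) || pair < 0) break
    rho_sum <- rho_sum + pair
  }
  max(1, round(n * m / (1 + 2 * rho_sum)))
}

#' Posterior point and interval summaries
#'
#' The point estimate is the posterior median; the interval is the central
#' credible interval with endpoints at the `(1 - level)/2` and
#' `1 - (1 - level)/2` empirical percentiles (linear interpolation between
#' order statistics, R quantile type 7).
#'
#' @param draws An `nof1_draws` object, or a numeric matrix of draws with
#'   column names.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return Tibble with columns `parameter`, `median`, `lower`, `upper`,
#'   `mean`, `ess`.
#' @export
summarize_draws <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (inherits(draws, "nof1_draws")) {
    m <- as.matrix(draws)
    ess <- vapply(seq_along(draws$par_names), function(j) {
      ess_basic(purrr::map(draws$chains, ~ .x[, j]))
    }, numeric(1))
  } else {
    m <- as.matrix(draws)
    ess <- rep(NA_real_, ncol(m))
  }
  a <- (1 - level) / 2
  qs <- apply(m, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  tibble::tibble(
    parameter = colnames(m),
    median = unname(qs[2, ]),
    lower = unname(qs[1, ]),
    upper = unname(qs[3, ]),
    mean = unname(colMeans(m)),
    ess = ess
  )
}

#' Posterior probability of an event
#'
#' Fraction of posterior draws satisfying a predicate, with its Monte Carlo
#' standard error.
#'
#' @param draws An `nof1_draws` object or a draws matrix.
#' @param predicate Function taking the draws matrix (columns = parameters)
#'   and returning one logical per draw, e.g.
#'   `\(d) d[, "delta[2]"] < 0`.
#' @return Tibble with columns `prob`, `mcse`, `n`.
#' @export
prob_event <- function(draws, predicate) {
  m <- as.matrix(draws)
  ok <- predicate(m)
  stopifnot(is.logical(ok), length(ok) == nrow(m))
  p <- mean(ok)
  tibble::tibble(prob = p, mcse = sqrt(p * (1 - p) / length(ok)),
                 n = length(ok))
}
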