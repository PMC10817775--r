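# Synthetic multi-individual N-of-1 datasets with known ground truth,
# emulating a diet-trial design: a 2-week usual-diet baseline, then ABAB or
# BABA sequences of two experimental diets in 8-week periods with weekly
# bounded outcomes, AR(1) noise, and three completion strata.

#' Second-level (population) parameters for simulation
#'
#' Defaults describe the simulated diet-trial scenario: a usual-diet
#' reference level near the T-score population mean, both experimental
#' diets reducing the outcome by 3 points on average, moderate
#' between-individual effect heterogeneity, AR(1) autocorrelation 0.4 and
#' residual standard deviation 5.
#'
#' @param d Mean treatment effects `d_k`, k = 2..K (outcome units).
#' @param m Mean intercept (reference-treatment level).
#' @param b Mean trend slope per week.
#' @param ze Mean Fisher-z autocorrelation (`fisher_z(0.4)` by default).
#' @param sigma Residual standard deviation.
#' @param sigma_delta,sigma_beta,sigma_mu,sigma_ze Between-individual
#'   standard deviations (0 = that parameter is identical across
#'   individuals).
#' @param rho_mu_delta Intercept-effect correlation; when nonzero,
#'   individual `(mu_i, delta_i)` are drawn from [build_sigma_mu_delta()].
#' @return A list of class `nof1_hyper`.
#' @export
hyper_params <- function(d = c(-3, -3), m = 50, b = 0, ze = fisher_z(0.4),
                         sigma = 5, sigma_delta = 2, sigma_beta = 0,
                         sigma_mu = 5, sigma_ze = 0, rho_mu_delta = 0) {
  structure(list(d = d, m = m, b = b, ze = ze, sigma = sigma,
                 sigma_delta = sigma_delta, sigma_beta = sigma_beta,
                 sigma_mu = sigma_mu, sigma_ze = sigma_ze,
                 rho_mu_delta = rho_mu_delta),
            class = "nof1_hyper")
}

#' Dropout and missingness model for simulation
#'
#' Completion strata are drawn with the given base probabilities (defaults:
#' the 21/54 full, 9/54 early, 24/54 withdrawal split).  A positive
#' `mnar_shift` tilts the withdrawal probability by the individual's
#' realized treatment benefit (less benefit, earlier dropout), making the
#' missingness informative.  `intermittent_rate` is the probability that a
#' retained measurement is missing at random.
#'
#' @param p_stratum Base probabilities `c(full, early, withdrawal)`.
#' @param mnar_shift Log-odds tilt of withdrawal per standard deviation of
#'   lost benefit.
#' @param intermittent_rate MAR missingness rate for retained rows.
#' @return A list of class `nof1_dropout`.
#' @export
dropout_model <- function(p_stratum = c(full = 21, early = 9,
                                        withdrawal = 24) / 54,
                          mnar_shift = 1, intermittent_rate = 0.1) {
  stopifnot(length(p_stratum) == 3, abs(sum(p_stratum) - 1) < 1e-8,
            intermittent_rate >= 0, intermittent_rate < 1)
  structure(list(p_stratum = p_stratum, mnar_shift = mnar_shift,
                 intermittent_rate = intermittent_rate),
            class = "nof1_dropout")
}

# period treatments from an A/B sequence label; with three treatments the
# letters are the two experimental diets (codes 2/3), with two they are the
# experimental vs reference alternation (codes 2/1)
sequence_treatments <- function(sequence, n_periods, k = 3L) {
  lab <- strsplit(sequence, "")[[1]]
  if (length(lab) < n_periods || !all(lab %in% c("A", "B"))) {
    stop("sequence must be A/B labels covering all periods", call. = FALSE)
  }
  map <- if (k >= 3) c(A = 2L, B = 3L) else c(A = 2L, B = 1L)
  unname(map[lab[seq_len(n_periods)]])
}

#' Simulate one N-of-1 trial
#'
#' Generates weekly outcomes for a full design (baseline plus all
#' experimental periods) from the first-level model: mean path from the
#' contrast parameters (plus optional linear trend), AR(1) errors started
#' from their stationary distribution.  Values are truncated to the outcome
#' bounds; the number of truncated draws is recorded in the `truncations`
#' attribute.
#'
#' @param params A [single_trial_params()] object (contrast form).
#' @param design A [produce_design()] template.
#' @param sequence Period sequence, e.g. `"ABAB"` (A/B are the two
#'   experimental diets, treatment codes 2/3).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param bounds `c(lower, upper)` truncation bounds or `NULL`.
#' @param id Individual label.
#' @param spec A [model_spec()] controlling trend/autocorrelation form.
#' @return An [nof1_data] tibble for one individual.
#' @export
simulate_trial <- function(params, design = produce_design(),
                           sequence = "ABAB", seed = NULL, bounds = NULL,
                           id = "1",
                           spec = model_spec("contrast",
                                             autocorrelation = "ar_errors")) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sim <- sim_trial_rows(params, design, sequence, bounds, id, spec)
  out <- nof1_data(sim$rows, k = max(2L, length(params$delta) + 1L),
                   bounds = bounds)
  attr(out, "truncations") <- sim$truncations
  out
}

# plain-tibble generation core shared with simulate_population
sim_trial_rows <- function(params, design, sequence, bounds, id, spec) {
  K <- length(params$delta) + 1L
  trt_per <- sequence_treatments(sequence, design$n_periods, K)
  rows <- purrr::map(0:design$n_periods, function(p) {
    tibble::tibble(time = period_times(design, p), period = as.integer(p),
                   treatment = if (p == 0) 1L else trt_per[p])
  }) |> dplyr::bind_rows()
  y <- simulate_series(params, spec, rows$time, rows$treatment)
  truncations <- 0L
  if (!is.null(bounds)) {
    truncations <- sum(y < bounds[1] | y > bounds[2])
    y <- pmin(pmax(y, bounds[1]), bounds[2])
  }
  rows$value <- y
  rows$id <- id
  rows$sequence <- sequence
  list(rows = rows[, c("id", "time", "period", "treatment", "value",
                       "sequence")],
       truncations = truncations)
}

#' Simulate a population of N-of-1 trials with known truth
#'
#' Draws per-individual first-level parameters from the second-level
#' distributions (optionally with the structured intercept-effect
#' correlation), generates each trial, then applies the dropout model:
#' full completers keep all periods, early completers keep only the first
#' crossover (periods 1-2), withdrawals stop during period 1.  Retained
#' measurements are additionally set missing at random at the intermittent
#' rate.  Returns the dataset together with the generating truth for
#' recovery testing.
#'
#' @param hyper A [hyper_params()] object.
#' @param n Number of individuals.
#' @param design A [produce_design()] template.
#' @param dropout A [dropout_model()], or `NULL` for complete data.
#' @param seed Integer seed.
#' @param bounds Truncation bounds (`NULL` = none; recovery studies use
#'   wide/no bounds so truncation is negligible).
#' @param cov_name,cov_prob,cov_shift Optional binary between-individual
#'   covariate: name, Bernoulli probability, and additive shift of the mean
#'   effects `d` when the indicator is 1.
#' @return List with `data` (an [nof1_data] tibble) and `truth` (hyper
#'   parameters, per-individual realized parameters, strata, design).
#' @export
simulate_population <- function(hyper = hyper_params(), n = 54L,
                                design = produce_design(),
                                dropout = dropout_model(), seed = 1L,
                                bounds = NULL, cov_name = NULL,
                                cov_prob = 0.5, cov_shift = 0) {
  set.seed(as.integer(seed))
  K <- length(hyper$d) + 1L
  xcov <- if (!is.null(cov_name)) stats::rbinom(n, 1, cov_prob)

  # individual parameters from the second level
  if (hyper$rho_mu_delta != 0 && hyper$sigma_mu > 0 &&
      hyper$sigma_delta > 0) {
    S <- build_sigma_mu_delta(hyper$sigma_mu, hyper$sigma_delta,
                              hyper$rho_mu_delta, K)
    ch <- chol(S)
    Z <- matrix(stats::rnorm(n * K), n, K) %*% ch
    mu_i <- hyper$m + Z[, 1]
    delta_i <- matrix(hyper$d, n, K - 1, byrow = TRUE) +
      Z[, -1, drop = FALSE]
  } else {
    mu_i <- stats::rnorm(n, hyper$m, hyper$sigma_mu)
    delta_i <- matrix(stats::rnorm(n * (K - 1), rep(hyper$d, each = n),
                                   hyper$sigma_delta), n, K - 1)
  }
  if (!is.null(xcov)) {
    delta_i <- delta_i + outer(xcov, rep_len(cov_shift, K - 1))
  }
  beta_i <- stats::rnorm(n, hyper$b, hyper$sigma_beta)
  ze_i <- stats::rnorm(n, hyper$ze, hyper$sigma_ze)
  rho_i <- inv_fisher_z(ze_i)

  # stratum assignment, optionally tilted by realized benefit
  strat_names <- c("full", "early", "withdrawal")
  if (is.null(dropout)) {
    stratum <- rep("full", n)
  } else {
    lost <- if (hyper$sigma_delta > 0) {
      (delta_i[, 1] - hyper$d[1]) / hyper$sigma_delta
    } else rep(0, n)
    stratum <- vapply(seq_len(n), function(i) {
      w <- dropout$p_stratum
      w[3] <- w[3] * exp(dropout$mnar_shift * lost[i])
      sample(strat_names, 1, prob = w / sum(w))
    }, character(1))
  }

  ids <- sprintf("id%02d", seq_len(n))
  spec <- model_spec("contrast",
                     trend = if (hyper$sigma_beta > 0 || hyper$b != 0)
                       "linear" else "none",
                     autocorrelation = "ar_errors")
  # the (time, period, treatment) template is identical for everyone on the
  # same sequence; build it once per sequence
  template <- purrr::map(c(ABAB = "ABAB", BABA = "BABA"), function(sq) {
    trt_per <- sequence_treatments(sq, design$n_periods, K)
    purrr::map(0:design$n_periods, function(p) {
      tibble::tibble(time = period_times(design, p), period = as.integer(p),
                     treatment = if (p == 0) 1L else trt_per[p])
    }) |> dplyr::bind_rows()
  })
  trials <- vector("list", n)
  dropout_week <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    params <- single_trial_params(
      m = mu_i[i], delta = delta_i[i, ],
      beta = beta_i[i], rho_e = rho_i[i], sigma2 = hyper$sigma^2)
    sq <- if (i %% 2 == 1) "ABAB" else "BABA"
    d <- template[[sq]]
    y <- simulate_series(params, spec, d$time, d$treatment)
    if (!is.null(bounds)) y <- pmin(pmax(y, bounds[1]), bounds[2])
    d$value <- y
    d$id <- ids[i]
    d$sequence <- sq
    if (!is.null(dropout)) {
      if (stratum[i] == "early") {
        d <- d[d$period <= 2L, ]
      } else if (stratum[i] == "withdrawal") {
        p1 <- period_times(design, 1)
        dropout_week[i] <- sample(p1[-1], 1)  # at least one period-1 week
        d <- d[d$time < dropout_week[i], ]
      }
      miss <- stats::runif(nrow(d)) < dropout$intermittent_rate
      d$value[miss] <- NA_real_
    }
    trials[[i]] <- d
  }
  covariates <- if (!is.null(xcov)) {
    tibble::tibble(id = ids, !!cov_name := xcov)
  }
  data <- nof1_data(dplyr::bind_rows(trials), k = K, bounds = bounds,
                    covariates = covariates)
  truth <- list(
    hyper = hyper,
    individuals = tibble::tibble(
      id = ids, mu = mu_i, beta = beta_i, rho = rho_i,
      stratum = stratum, dropout_week = dropout_week,
      !!!stats::setNames(as.data.frame(delta_i),
                         sprintf("delta%d", 2:K))),
    design = design, seed = seed
  )
  if (!is.null(xcov)) truth$individuals[[cov_name]] <- xcov
  list(data = data, truth = truth)
}

#' Write a simulated dataset and its truth to disk
#'
#' @param sim Result of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(sim$data, file.path(dir, "trials.csv"))
  truth <- sim$truth
  truth$individuals <- as.data.frame(truth$individuals)
  truth$hyper <- unclass(truth$hyper)
  truth$design <- unclass(truth$design)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
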