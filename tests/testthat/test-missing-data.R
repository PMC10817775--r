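spec_ar <- model_spec("contrast", autocorrelation = "ar_errors")

test_that("conditional moments match the 3-dim normal conditioning oracle", {
  # interior missing point between two observed neighbours, rho = 0.5
  y <- c(48, NA, 53)
  d <- make_trial(y, treatments = rep(1L, 3), periods = rep(0L, 3))
  p <- single_trial_params(m = 50, delta = numeric(), rho_e = 0.5,
                           sigma2 = 2)
  mm <- mar_conditional_moments(d, p, spec_ar)
  # oracle: explicit multivariate-normal conditioning on the AR(1) covariance
  S <- ar1_covariance(0:2, 0.5, 2)
  obs <- c(1, 3)
  w <- solve(S[obs, obs], S[obs, 2])
  oracle_mean <- 50 + sum(w * (y[obs] - 50))
  oracle_var <- S[2, 2] - sum(S[2, obs] * w)
  expect_equal(mm$cond_mean, oracle_mean, tolerance = 1e-10)
  expect_equal(mm$cond_var, oracle_var, tolerance = 1e-10)
})

test_that("conditioning handles edges, gaps and independence", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 6
    rho <- runif(1, 0.05, 0.9)
    y <- runif(n, 40, 60)
    miss <- sample(1:n, 2)
    y_na <- y
    y_na[miss] <- NA
    d <- make_trial(y_na, treatments = rep(1L, n), periods = rep(0L, n))
    p <- single_trial_params(m = 50, delta = numeric(), rho_e = rho,
                             sigma2 = 3)
    mm <- mar_conditional_moments(d, p, spec_ar)
    S <- ar1_covariance(0:(n - 1), rho, 3)
    obs <- setdiff(1:n, miss)
    for (i in seq_along(mm$time)) {
      j <- mm$time[i] + 1
      w <- solve(S[obs, obs], S[obs, j])
      expect_equal(mm$cond_mean[i], 50 + sum(w * (y[obs] - 50)),
                   tolerance = 1e-8)
      expect_equal(mm$cond_var[i], S[j, j] - sum(S[j, obs] * w),
                   tolerance = 1e-8)
    }
  }
  # rho = 0: draws are independent N(M_j, sigma^2)
  d0 <- make_trial(c(40, NA, 60), treatments = rep(1L, 3),
                   periods = rep(0L, 3))
  p0 <- single_trial_params(m = 50, delta = numeric(), rho_e = 0, sigma2 = 4)
  mm0 <- mar_conditional_moments(d0, p0, spec_ar)
  expect_equal(mm0$cond_mean, 50)
  expect_equal(mm0$cond_var, 4)
})

test_that("imputation fills every slot and never alters observed values", {
  set.seed(15)
  d <- make_trial(c(50, NA, 47, NA, 52), treatments = rep(1L, 5),
                  periods = rep(0L, 5), bounds = c(34, 78))
  p <- single_trial_params(m = 50, delta = numeric(), rho_e = 0.3,
                           sigma2 = 4)
  filled <- impute_mar_draw(d, p, spec_ar)
  expect_false(anyNA(filled$value))
  expect_equal(filled$value[c(1, 3, 5)], c(50, 47, 52))
  expect_equal(filled$imputed, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_true(all(filled$value >= 34 & filled$value <= 78))
})

test_that("data augmentation leaves the parameter posterior unchanged", {
  # 5-observation toy trial with one missing value: augmented fit vs
  # analytic marginalization (likelihood on observed rows only)
  d <- make_trial(c(49, 51, NA, 53, 50), treatments = rep(c(1L, 2L), 3)[1:5],
                  bounds = NULL)
  spec <- model_spec("contrast", autocorrelation = "ar_errors")
  pri <- default_priors(spec, c(34, 78))
  cfg <- sampler_config(chains = 2, warmup = 400, draws = 1200, seed = 17)
  m_aug <- assemble_single_trial(d, spec, pri, impute_missing = TRUE)
  m_marg <- assemble_single_trial(d, spec, pri, impute_missing = FALSE)
  expect_true("y_mis[3]" %in% m_aug$pars$name)
  dr_aug <- as.matrix(sample_posterior(m_aug, cfg))
  dr_marg <- as.matrix(sample_posterior(m_marg, cfg))
  for (par in c("m", "delta[2]")) {
    se <- sd(dr_marg[, par]) * sqrt(2 / 300)  # generous ESS-based error
    expect_lt(abs(mean(dr_aug[, par]) - mean(dr_marg[, par])), 4 * se)
  }
})

test_that("Rubin pooling matches the standard formulas", {
  out <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(out$estimate, 2)
  expect_equal(out$total_variance, 1 + (1 + 1 / 3) * 1)
  # M = 1: no between-imputation term
  one <- rubin_pool(5, 2)
  expect_equal(one$estimate, 5)
  expect_equal(one$total_variance, 2)
  # identical estimates: between-variance zero
  same <- rubin_pool(rep(4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$total_variance, 3)
  expect_error(rubin_pool(numeric(0), numeric(0)), "no estimates")
})

test_that("pooled variance never falls below the within-imputation mean", {
  set.seed(16)
  for (rep in 1:25) {
    M <- sample(2:8, 1)
    est <- rnorm(M)
    v <- runif(M, 0.1, 2)
    out <- rubin_pool(est, v)
    expect_gte(out$total_variance, mean(v))
    # independent evaluation of the df adjustment
    B <- var(est)
    expect_equal(out$df, (M - 1) * (1 + mean(v) / ((1 + 1 / M) * B))^2)
  }
})

test_that("stratum-specific imputation produces M valid completed sets", {
  set.seed(18)
  sim <- simulate_population(hyper_params(d = c(-3, -3), sigma_mu = 3),
                             n = 12, design = produce_design(2, 4, 7),
                             dropout = dropout_model(intermittent_rate = 0.1),
                             seed = 19, bounds = c(34, 78))
  imp <- impute_mnar_by_group(
    sim$data, M = 3, design = produce_design(2, 4, 7),
    config = sampler_config(chains = 1, warmup = 150, draws = 150,
                            seed = 5))
  expect_length(imp$completed, 3)
  obs <- tibble::as_tibble(sim$data)
  for (m in 1:3) {
    cd <- tibble::as_tibble(imp$completed[[m]])
    expect_false(anyNA(cd$value))
    expect_true(all(cd$value >= 34 & cd$value <= 78))
    # observed cells identical across completed datasets
    key <- paste(obs$id, obs$time)
    ckey <- paste(cd$id, cd$time)
    expect_equal(cd$value[match(key[!is.na(obs$value)], ckey)],
                 obs$value[!is.na(obs$value)])
    # minimum-measurement rules hold
    counts <- dplyr::count(cd, id, period)
    expect_true(all(counts$n[counts$period > 0] >= 6))
    expect_true(all(table(cd$id[cd$period == 0]) >= 1))
  }
  # a fully complete individual is identical across imputations
  cc <- classify_completion(sim$data)
  full_ids <- cc$id[cc$stratum == "full"]
  done <- full_ids[vapply(full_ids, function(i) {
    !anyNA(obs$value[obs$id == i])
  }, logical(1))]
  if (length(done) > 0) {
    i <- done[1]
    v1 <- tibble::as_tibble(imp$completed[[1]])
    v2 <- tibble::as_tibble(imp$completed[[2]])
    expect_equal(v1$value[v1$id == i], v2$value[v2$id == i])
  }
})

test_that("withdrawals are imputed from their own stratum's posterior", {
  # two well-separated strata: completers improve by 10, withdrawals by 0.
  # imputed period-2+ values for a withdrawal must track the withdrawal
  # stratum's (absent) benefit, not the completers' large one.
  set.seed(20)
  design <- produce_design(2, 4, 7)
  mk_id <- function(id, delta, periods_kept) {
    p <- single_trial_params(m = 55, delta = c(delta, delta), rho_e = 0,
                             sigma2 = 1)
    tr <- simulate_trial(p, design, sequence = "ABAB", seed = NULL,
                         bounds = c(34, 78), id = id,
                         spec = model_spec("contrast"))
    d <- tibble::as_tibble(tr)
    d[d$period <= periods_kept, ]
  }
  rows <- dplyr::bind_rows(
    purrr::map(1:6, ~ mk_id(sprintf("full%d", .x), -10, 4)),
    purrr::map(1:6, ~ mk_id(sprintf("wd%d", .x), 0, 1))
  )
  data <- nof1_data(rows, k = 3, bounds = c(34, 78))
  imp <- impute_mnar_by_group(
    data, M = 4, design = design,
    config = sampler_config(chains = 1, warmup = 200, draws = 200,
                            seed = 11))
  done <- dplyr::bind_rows(purrr::map(imp$completed, tibble::as_tibble))
  # period 3 repeats the diet the withdrawals actually tried (treatment 2),
  # so its effect is informed by withdrawal-stratum data; diet 3 is never
  # observed in that stratum and stays prior-driven
  wd_imp <- done[grepl("^wd", done$id) & done$period == 3, ]
  expect_equal(unique(wd_imp$treatment), 2L)
  full_imp_mean <- 55 - 10
  wd_mean <- mean(wd_imp$value)
  # imputed withdrawal values sit near their own stratum mean (55),
  # far from the completers' diet mean (45)
  expect_gt(wd_mean, 51)
  expect_lt(abs(wd_mean - 55), 2.5)
  expect_gt(abs(wd_mean - full_imp_mean), 5)
})
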