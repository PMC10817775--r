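test_that("structured covariance has the forced 0.5 contrast correlation", {
  S2 <- build_sigma_mu_delta(2, 3, 0.4, K = 2)
  expect_equal(S2, matrix(c(4, 0.4 * 6, 0.4 * 6, 9), 2, 2))
  S3 <- build_sigma_mu_delta(1, 1, 0, K = 3)
  expect_equal(S3, matrix(c(1, 0, 0, 0, 1, 0.5, 0, 0.5, 1), 3, 3))
  # implied correlation between effect components is exactly 0.5
  set.seed(1)
  for (rep in 1:20) {
    K <- sample(3:6, 1)
    S <- build_sigma_mu_delta(runif(1, 0.5, 5), runif(1, 0.5, 5),
                              runif(1, -0.5, 0.5), K)
    C <- stats::cov2cor(S)[-1, -1]
    expect_equal(unique(C[upper.tri(C)]), 0.5)
  }
})

test_that("inadmissible intercept-effect correlations are rejected", {
  # eigenvalue oracle: the implied matrix has a negative eigenvalue
  S <- matrix(c(1, 0.999, 0.999,
                0.999, 1, 0.5,
                0.999, 0.5, 1), 3, 3)
  expect_lt(min(eigen(S, symmetric = TRUE)$values), 0)
  expect_error(build_sigma_mu_delta(1, 1, 0.999, K = 3),
               "positive definite")
  expect_silent(build_sigma_mu_delta(1, 1, 0.86, K = 3))
})

test_that("Fisher-z transform is the exact inverse pair", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(inv_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(abs(inv_fisher_z(c(-50, -5, 0, 5, 50))) < 1))
  expect_error(fisher_z(1), "< 1")
})

test_that("carryover covariate decays with the declared half-life", {
  expect_equal(carryover_covariate(10, 10, 1), 1)
  expect_equal(carryover_covariate(11, 10, 1), 0.5)
  expect_equal(carryover_covariate(12, 10, 1), 0.25)
  expect_equal(carryover_covariate(12, 10, 2), 0.5)
  expect_error(carryover_covariate(9, 10, 1), ">=")
  expect_equal(total_effect(-3, 0.5), -4.5)
})

test_that("add_carryover_covariate marks post-crossover periods", {
  d <- make_design_trial(len = 3L, treatments = c(2L, 3L, 2L, 3L))
  dc <- add_carryover_covariate(d, half_life = 1, into = c(1L, 2L, 3L))
  df <- tibble::as_tibble(dc)
  # first period has no preceding experimental diet
  expect_true(all(df$z_carry[df$period <= 1] == 0))
  p2 <- df[df$period == 2, ]
  expect_equal(p2$z_carry, 2^-(p2$time - min(p2$time)))
  expect_equal(unique(p2$carry_from), 2L)
})

test_that("a one-individual multilevel model collapses to the single trial", {
  d <- make_trial(c(50, 47, 52, 46, 49), treatments = c(1L, 2L, 1L, 2L, 1L))
  spec <- model_spec("contrast", autocorrelation = "ar_errors")
  priors <- default_priors(spec, c(34, 78))
  lvl <- level_spec(intercepts = "fixed", effects = "fixed",
                    correlations = "fixed", variances = "fixed")
  model <- assemble_multilevel(d, spec, lvl, priors)
  st <- c("mu[p1]" = 49, "delta[p1,2]" = -3, "rho[p1]" = 0.3,
          "sigma[p1]" = 2.5)
  p <- single_trial_params(m = 49, delta = -3, rho_e = 0.3, sigma2 = 2.5^2)
  manual_priors <- -log(78 - 34) - log(2 * 44) - log(2) - log(1000)
  expect_equal(model_log_density(model, st),
               loglik(p, spec, d) + manual_priors)
})

test_that("common parameters are shared across identical individuals", {
  d1 <- tibble::as_tibble(make_trial(c(50, 47, 52, 46),
                                     treatments = c(1L, 2L, 1L, 2L)))
  d2 <- d1
  d2$id <- "p2"
  both <- nof1_data(rbind(d1, d2), bounds = NULL)
  spec <- model_spec("contrast")
  lvl <- level_spec(intercepts = "common", effects = "common",
                    correlations = "common", variances = "common")
  model <- assemble_multilevel(both, spec, lvl,
                               default_priors(spec, c(34, 78)))
  st <- c(mu = 49, "d[2]" = -3, sigma = 2)
  p <- single_trial_params(m = 49, delta = -3, sigma2 = 4)
  one <- nof1_data(d1, bounds = NULL)
  expect_equal(model_log_density(model, st),
               2 * loglik(p, spec, one) - log(44) - log(88) - log(1000))
})

test_that("random effects collapse onto their mean as sigma_delta -> 0", {
  set.seed(21)
  sim <- simulate_population(hyper_params(d = -3, sigma_delta = 2,
                                          sigma_mu = 3),
                             n = 5, design = produce_design(2, 2, 5),
                             dropout = NULL, seed = 31)
  spec <- model_spec("contrast", autocorrelation = "ar_errors")
  model <- assemble_multilevel(sim$data, spec,
                               level_spec(intercepts = "fixed",
                                          effects = "random"),
                               default_priors(spec, NULL))
  # pin the effect heterogeneity at (nearly) zero
  i <- match("sigma_delta", model$pars$name)
  model$pars$init[i] <- 1e-4
  model$pars$lower[i] <- 1e-4 * (1 - 1e-6)
  model$pars$upper[i] <- 1e-4 * (1 + 1e-6)
  dr <- sample_posterior(model, sampler_config(chains = 1, warmup = 150,
                                               draws = 150, seed = 4))
  m <- as.matrix(dr)
  dcols <- grep("^delta\\[", colnames(m), value = TRUE)
  spread <- sapply(dcols, function(cn) max(abs(m[, cn] - m[, "d[2]"])))
  expect_lt(max(spread), 1e-2)
})

test_that("subgroup effects are per-draw linear combinations", {
  m <- cbind("d0[2]" = c(-2, -3, -4), "d_girl[2]" = c(-1, 0, 1))
  dr <- fake_draws(m)
  se <- subgroup_effect(dr, c(girl = 1), c(girl = 0))
  expect_equal(se$effect1, c(-3, -3, -3))
  expect_equal(se$effect2, c(-2, -3, -4))
  expect_equal(se$difference, m[, "d_girl[2]"])
  same <- subgroup_effect(dr, c(girl = 1), c(girl = 1))
  expect_true(all(same$difference == 0))
  expect_error(subgroup_effect(dr, c(boy = 1), c(boy = 0)), "unknown")
})

test_that("a two-group covariate shifts the recovered effect means", {
  set.seed(33)
  sim <- simulate_population(hyper_params(d = -2, sigma_delta = 0.8,
                                          sigma_mu = 2, sigma = 2),
                             n = 16, design = produce_design(2, 4, 7),
                             dropout = NULL, seed = 13, cov_name = "girl",
                             cov_prob = 0.5, cov_shift = -3)
  spec <- model_spec("contrast", autocorrelation = "ar_errors")
  lvl <- level_spec(intercepts = "fixed", effects = "random",
                    effect_covariates = "girl")
  dr <- fit_meta(sim$data, spec, lvl,
                 priors = default_priors(spec, NULL),
                 config = sampler_config(chains = 1, warmup = 300,
                                         draws = 400, seed = 6))
  se <- subgroup_effect(dr, c(girl = 1), c(girl = 0))
  expect_lt(median(se$difference), -1)  # girls improve more
  expect_lt(abs(median(se$effect2) - (-2)), 1.5)
})

test_that("parameter recovery: hyper effect mean found at moderate size", {
  sim <- simulate_population(hyper_params(d = -3, sigma_delta = 2,
                                          sigma_mu = 4),
                             n = 10, design = produce_design(2, 4, 7),
                             dropout = NULL, seed = 71)
  spec <- model_spec("contrast", autocorrelation = "ar_errors")
  dr <- fit_meta(sim$data, spec,
                 priors = default_priors(spec, NULL),
                 config = sampler_config(chains = 1, warmup = 300,
                                         draws = 300, seed = 7))
  s <- summarize_draws(dr)
  d2 <- s$median[s$parameter == "d[2]"]
  expect_lt(abs(d2 - (-3)), 1.5)
  rho <- s$median[s$parameter == "rho"]
  expect_lt(abs(rho - 0.4), 0.25)
})

test_that("recovered autocorrelations stay inside (-1, 1)", {
  sim <- simulate_population(hyper_params(d = -3, sigma_ze = 0.3),
                             n = 4, design = produce_design(2, 2, 6),
                             dropout = NULL, seed = 9)
  spec <- model_spec("contrast", autocorrelation = "ar_errors")
  lvl <- level_spec(intercepts = "fixed", effects = "random",
                    correlations = "random")
  dr <- fit_meta(sim$data, spec, lvl, priors = default_priors(spec, NULL),
                 config = sampler_config(chains = 1, warmup = 150,
                                         draws = 200, seed = 3))
  m <- as.matrix(dr)
  zcols <- grep("^ze\\[", colnames(m), value = TRUE)
  expect_true(length(zcols) == 4)
  rhos <- inv_fisher_z(m[, zcols])
  expect_true(all(abs(rhos) < 1))
})
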