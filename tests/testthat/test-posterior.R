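spec_iid <- model_spec("contrast")

test_that("a point-mass posterior predicts from the sampling distribution", {
  set.seed(22)
  m <- cbind("m" = rep(50, 3000), "delta[2]" = rep(-3, 3000),
             "sigma" = rep(2, 3000))
  dr <- fake_draws(m)
  dr$meta <- list(spec = spec_iid, K = 2L)
  design <- data.frame(time = 0:9, treatment = rep(c(1L, 2L), 5))
  pred <- posterior_predictive(dr, design)
  expect_equal(dim(pred), c(3000, 10))
  mu <- 50 + ifelse(design$treatment == 2, -3, 0)
  expect_equal(colMeans(pred), mu, tolerance = 0.15)
  expect_equal(unname(apply(pred, 2, sd)), rep(2, 10), tolerance = 0.1)
})

test_that("predictive variance adds parameter and sampling uncertainty", {
  set.seed(23)
  # law of total variance: predictive var >= mean per-draw sampling var
  m <- cbind("m" = rnorm(2000, 50, 3), "delta[2]" = rep(0, 2000),
             "sigma" = rep(2, 2000))
  dr <- fake_draws(m)
  dr$meta <- list(spec = spec_iid, K = 2L)
  pred <- posterior_predictive(dr, data.frame(time = 0, treatment = 1L))
  expect_gt(var(pred[, 1]), 4)                     # > sigma^2 alone
  expect_equal(var(pred[, 1]), 4 + 9, tolerance = 0.15 * 13)
})

test_that("predictive intervals are wider than parameter intervals", {
  set.seed(24)
  d <- make_trial(rnorm(12, 50, 3), treatments = rep(c(1L, 2L), 6))
  dr <- fit_single(d, spec = spec_iid,
                   priors = default_priors(spec_iid, NULL),
                   config = sampler_config(chains = 1, warmup = 200,
                                           draws = 600, seed = 8))
  s <- summarize_draws(dr)
  par_width <- with(s[s$parameter == "m", ], upper - lower)
  pred <- posterior_predictive(dr, data.frame(time = 0, treatment = 1L))
  pred_q <- quantile(pred[, 1], c(0.025, 0.975))
  expect_gt(diff(pred_q), par_width)
})

test_that("unknown treatments in the new design are rejected", {
  dr <- fake_draws(cbind("m" = 1, "delta[2]" = 0, "sigma" = 1))
  dr$meta <- list(spec = spec_iid, K = 2L)
  expect_error(posterior_predictive(dr, data.frame(time = 0, treatment = 3L)),
               "unknown treatment")
})

test_that("posterior predictive p values behave at the extremes", {
  set.seed(25)
  y <- rnorm(10, 50, 2)
  d <- make_trial(y, treatments = rep(c(1L, 2L), 5))
  m <- cbind("m" = rnorm(400, 50, 0.3), "delta[2]" = rnorm(400, 0, 0.3),
             "sigma" = runif(400, 1.8, 2.2))
  dr <- fake_draws(m)
  dr$meta <- list(spec = spec_iid, K = 2L)
  # constant statistic: ties count as exceedance
  expect_equal(ppc_pvalue(dr, d, statistic = function(y, th) 1), 1)
  # observed data far above anything the model replicates
  d_hi <- make_trial(y + 100, treatments = rep(c(1L, 2L), 5), bounds = NULL)
  expect_lt(ppc_pvalue(dr, d_hi), 0.01)
  # data consistent with the model: p value not extreme
  p <- ppc_pvalue(dr, d)
  expect_gt(p, 0.02)
  expect_lt(p, 0.98)
  expect_error(ppc_pvalue(dr, d, statistic = function(y, th) NaN),
               "nonfinite")
})

test_that("responder classification follows both probability criteria", {
  # point mass at -5: certain meaningful improvement
  r <- classify_responder(rep(-5, 100), mcid = 3)
  expect_equal(r$p_improvement, 1)
  expect_equal(r$p_worsening, 0)
  expect_true(r$responder)
  # wide symmetric draws: fails both criteria
  set.seed(26)
  r2 <- classify_responder(rnorm(4000, 0, 20), mcid = 3)
  expect_false(r2$responder)
  expect_lt(r2$p_improvement, 0.5)
  expect_gt(r2$p_worsening, 0.1)
  # higher-is-better flips the direction
  r3 <- classify_responder(rep(5, 100), mcid = 3, direction = "higher")
  expect_true(r3$responder)
  expect_error(classify_responder(numeric(0)), "no draws")
})

test_that("shifting draws toward benefit never breaks responder status", {
  set.seed(27)
  base <- rnorm(2000, -3.5, 1)
  r_base <- classify_responder(base)
  shifted <- classify_responder(base - 2)
  expect_true(r_base$responder)
  expect_true(shifted$responder)
  expect_gte(shifted$p_improvement, r_base$p_improvement)
  expect_lte(shifted$p_worsening, r_base$p_worsening)
})

test_that("benefit/harm tables report medians, intervals and Pr(<0)", {
  set.seed(28)
  n <- 5000
  m <- cbind("m[1]" = rnorm(n, 50, 1), "m[2]" = rnorm(n, 47, 1),
             "m[3]" = rnorm(n, 47, 1))
  dr <- fake_draws(m)
  tab <- benefit_harm_table(dr, list("SCD v UD" = c(2, 1),
                                     "MSCD v UD" = c(3, 1),
                                     "SCD v MSCD" = c(2, 3)))
  expect_equal(tab$comparison, c("SCD v UD", "MSCD v UD", "SCD v MSCD"))
  expect_equal(tab$median[1], -3, tolerance = 0.1)
  expect_gt(tab$pr_less_0[1], 0.95)
  # independent identically distributed arms: Pr(<0) near one half
  expect_equal(tab$pr_less_0[3], 0.5, tolerance = 0.05)
  # a treatment against itself: degenerate zero difference
  self <- benefit_harm_table(dr, list("self" = c(2, 2)))
  expect_equal(self$median, 0)
  expect_equal(self$lower, 0)
  # medians are antisymmetric under reversing the comparison
  fwd <- benefit_harm_table(dr, list(x = c(2, 1)))
  rev <- benefit_harm_table(dr, list(x = c(1, 2)))
  expect_equal(fwd$median, -rev$median)
  expect_error(benefit_harm_table(dr, list(bad = c(9, 1))), "treatment 9")
})

test_that("contrast and hyperparameter draws feed the same table shape", {
  m <- cbind("delta[2]" = c(-4, -2, -3), "delta[3]" = c(-1, 0, 1))
  tab <- benefit_harm_table(fake_draws(m),
                            list("2v1" = c(2, 1), "2v3" = c(2, 3)))
  expect_equal(tab$median, c(-3, -3))
  mh <- cbind("d[2]" = c(-4, -2, -3))
  tabh <- benefit_harm_table(fake_draws(mh), list("2v1" = c(2, 1)))
  expect_equal(tabh$median, -3)
})
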