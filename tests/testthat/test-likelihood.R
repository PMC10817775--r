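spec_ar <- model_spec("contrast", autocorrelation = "ar_errors")
spec_iid <- model_spec("contrast")

test_that("marginal moments follow the stationary AR(1) formulas", {
  p <- single_trial_params(m = 50, delta = -3, sigma2 = 4)
  mm <- marginal_moments(p, spec_iid, time = 0, treatment = 2)
  expect_equal(mm$mean, 47)
  expect_equal(mm$variance, 4)
  p2 <- single_trial_params(m = 50, delta = -3, rho_e = 0.6, sigma2 = 4)
  expect_equal(marginal_moments(p2, spec_ar, 0, 1)$variance, 6.25)
})

test_that("stationary variance matches a long simulated AR(1) sequence", {
  # empirical oracle: variance of a simulated stationary AR(1) sequence
  set.seed(42)
  n <- 2e5
  rho <- 0.6
  sigma <- 2
  e <- stats::filter(rnorm(n, 0, sigma), rho, method = "recursive",
                     init = rnorm(1, 0, sigma / sqrt(1 - rho^2)))
  expect_lt(abs(var(as.numeric(e)) - 6.25) / 6.25, 0.03)
})

test_that("marginal variance is monotone in |rho| for fixed sigma2", {
  vs <- sapply(c(0, 0.3, 0.6, 0.9), function(r) {
    p <- single_trial_params(m = 0, delta = 0, rho_e = r, sigma2 = 1)
    marginal_moments(p, spec_ar, 0, 1)$variance
  })
  expect_true(all(diff(vs) > 0))
})

test_that("with rho = 0 the exact likelihood is the independent one", {
  d <- make_trial(c(50, 47, 52, 46), treatments = c(1L, 2L, 1L, 2L))
  p <- single_trial_params(m = 49, delta = -2, sigma2 = 5)
  ll <- loglik(p, spec_ar, d)
  expect_equal(ll, sum(dnorm(d$value, 49 + c(0, -2, 0, -2), sqrt(5),
                             log = TRUE)))
  spec_prod <- model_spec("contrast", autocorrelation = "ar_errors",
                          likelihood_mode = "paper_product")
  expect_equal(ll, loglik(p, spec_prod, d))
})

test_that("exact AR(1) likelihood matches the dense MVN oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    rho <- runif(1, -0.9, 0.9)
    s2 <- runif(1, 0.2, 9)
    m <- runif(1, 30, 70)
    del <- runif(1, -10, 10)
    trts <- sample(1:2, n, replace = TRUE)
    y <- runif(n, 30, 70)
    d <- make_trial(y, treatments = trts, periods = seq_len(n) - 1L)
    p <- single_trial_params(m = m, delta = del, rho_e = rho, sigma2 = s2)
    mu <- m + ifelse(trts == 2, del, 0)
    expect_equal(loglik(p, spec_ar, d),
                 mvn_logdens(y, mu, ar1_covariance(d$time, rho, s2)),
                 tolerance = 1e-10)
  }
})

test_that("missing rows are marginalized exactly (gap-aware conditionals)", {
  set.seed(12)
  for (rep in 1:20) {
    y <- runif(6, 40, 60)
    miss <- sort(sample(2:5, 2))
    y_na <- y
    y_na[miss] <- NA
    d <- make_trial(y_na, treatments = rep(1L, 6), periods = rep(0L, 6))
    rho <- runif(1, 0.05, 0.9)
    p <- single_trial_params(m = 50, delta = numeric(), mk = NULL,
                             rho_e = rho, sigma2 = 2)
    keep <- setdiff(1:6, miss)
    Sigma <- ar1_covariance(0:5, rho, 2)[keep, keep]
    expect_equal(loglik(p, spec_ar, d),
                 mvn_logdens(y[keep], rep(50, length(keep)), Sigma),
                 tolerance = 1e-10)
  }
})

test_that("printed toy case: n = 4, rho = 0.5 equals the 4-dim MVN", {
  y <- c(48, 51.5, 47, 50)
  d <- make_trial(y, treatments = c(1L, 2L, 1L, 2L))
  p <- single_trial_params(m = 49, delta = 1, rho_e = 0.5, sigma2 = 1)
  mu <- 49 + c(0, 1, 0, 1)
  expect_equal(loglik(p, spec_ar, d),
               mvn_logdens(y, mu, ar1_covariance(0:3, 0.5, 1)),
               tolerance = 1e-10)
})

test_that("arm and contrast forms agree when mk = m + delta_k", {
  d <- make_trial(c(50, 47, 52, 46, 49), treatments = c(1L, 2L, 3L, 2L, 1L),
                  k = 3)
  pc <- single_trial_params(m = 49, delta = c(-2, 1), rho_e = 0.4,
                            sigma2 = 3)
  pa <- single_trial_params(mk = c(49, 47, 50), rho_e = 0.4, sigma2 = 3)
  spec_arm <- model_spec("arm", autocorrelation = "ar_errors")
  expect_equal(loglik(pc, spec_ar, d), loglik(pa, spec_arm, d))
})

test_that("lagged-outcome model matches a direct conditional computation", {
  y <- c(50, 53, 49)
  d <- make_trial(y, treatments = c(1L, 2L, 1L))
  rho <- 0.4
  s2 <- 2
  p <- single_trial_params(m = 48, delta = 2, rho_y = rho, sigma2 = s2)
  spec_ary <- model_spec("contrast", autocorrelation = "ar_outcomes")
  mu <- 48 + c(0, 2, 0)
  manual <- dnorm(y[1], mu[1] / (1 - rho), sqrt(s2 / (1 - rho^2)),
                  log = TRUE) +
    dnorm(y[2], mu[2] + rho * y[1], sqrt(s2), log = TRUE) +
    dnorm(y[3], mu[3] + rho * y[2], sqrt(s2), log = TRUE)
  expect_equal(loglik(p, spec_ary, d), manual)
})

test_that("discrete-family likelihoods reduce to known log masses", {
  db <- make_trial(c(0, 1, 1, 0), treatments = c(1L, 2L, 1L, 2L))
  spec_b <- model_spec("contrast", family = "bernoulli_logit")
  p0 <- single_trial_params(m = 0, delta = 0, sigma2 = 1)
  expect_equal(glm_loglik(p0, spec_b, db), 4 * log(0.5))
  dp <- make_trial(c(0, 2), treatments = c(1L, 2L))
  spec_p <- model_spec("contrast", family = "poisson_log")
  p1 <- single_trial_params(m = 0, delta = 0, sigma2 = 1)
  # log lambda = 0, outcome 0: mass exp(-1)
  expect_equal(glm_loglik(p1, spec_p, make_trial(0, treatments = 1L)), -1)
  expect_equal(glm_loglik(p1, spec_p, dp),
               sum(dpois(c(0, 2), 1, log = TRUE)))
  # identity-link normal is the normal likelihood
  dn <- make_trial(c(50, 47), treatments = c(1L, 2L))
  pn <- single_trial_params(m = 49, delta = -2, sigma2 = 4)
  expect_equal(glm_loglik(pn, spec_iid, dn), loglik(pn, spec_iid, dn))
  expect_error(glm_loglik(p0, spec_b, make_trial(0.5, treatments = 1L)),
               "integer")
})

test_that("poisson log-likelihood is concave in the mean parameter", {
  d <- make_trial(c(1, 3, 0, 2), treatments = rep(1L, 4), periods = rep(0L, 4))
  spec_p <- model_spec("contrast", family = "poisson_log")
  grid <- seq(-1, 1.5, length.out = 25)
  ll <- sapply(grid, function(m) {
    glm_loglik(single_trial_params(m = m, delta = numeric(), sigma2 = 1),
               spec_p, d)
  })
  expect_true(all(diff(diff(ll)) < 1e-8))
})

test_that("degenerate inputs fail loudly", {
  all_na <- make_trial(c(NA, NA), treatments = c(1L, 2L))
  p <- single_trial_params(m = 0, delta = 0, sigma2 = 1)
  expect_error(loglik(p, spec_iid, all_na), "no non-missing")
  expect_error(single_trial_params(m = 0, delta = 0, rho_e = 1), "1")
  expect_error(single_trial_params(m = 0, delta = 0, sigma2 = 0), "sigma2")
})
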