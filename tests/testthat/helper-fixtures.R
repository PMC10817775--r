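# fixtures and independent oracles built in code

# small well-formed trial: baseline + alternating periods, weekly times
make_trial <- function(values, treatments = NULL, periods = NULL,
                       id = "p1", bounds = NULL, k = 2L) {
  n <- length(values)
  if (is.null(treatments)) treatments <- rep(c(1L, 2L), length.out = n)
  if (is.null(periods)) periods <- seq_len(n) - 1L
  nof1_data(data.frame(id = id, time = seq_len(n) - 1, period = periods,
                       treatment = treatments, value = values),
            k = k, bounds = bounds)
}

# an ABAB-style trial: 2 baseline weeks + n_periods periods of len weeks
make_design_trial <- function(id = "p1", n_periods = 4L, len = 8L,
                              treatments = c(2L, 3L, 2L, 3L),
                              value = 50, k = 3L, bounds = NULL) {
  rows <- data.frame(id = id, time = 0:1, period = 0L, treatment = 1L)
  t0 <- 2
  for (p in seq_len(n_periods)) {
    rows <- rbind(rows, data.frame(id = id, time = t0 + seq_len(len) - 1,
                                   period = p, treatment = treatments[p]))
    t0 <- t0 + len
  }
  rows$value <- rep_len(value, nrow(rows))
  nof1_data(rows, k = k, bounds = bounds)
}

# dense multivariate-normal log density via explicit covariance:
# independent oracle for the AR(1) likelihood
ar1_covariance <- function(times, rho, sigma2) {
  v <- sigma2 / (1 - rho^2)
  v * rho^abs(outer(times, times, "-"))
}

mvn_logdens <- function(y, mu, Sigma) {
  n <- length(y)
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -sum(log(diag(ch))) - 0.5 * sum(z^2) - n / 2 * log(2 * pi)
}

# minimal nof1_draws-like object from a plain matrix (one chain)
fake_draws <- function(m) {
  structure(list(chains = list(as.matrix(m)), par_names = colnames(m),
                 config = sampler_config(chains = 1, warmup = 0,
                                         draws = nrow(m)),
                 meta = NULL),
            class = "nof1_draws")
}
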