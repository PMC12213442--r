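# Independent brute-force oracles used across test files. These are kept
# deliberately naive (double loops, explicit linear solves) and never share
# code with the package implementation.

# sample ACF by explicit double loop, series-mean centred
acf_brute <- function(x, max_lag) {
  n <- length(x)
  m <- mean(x)
  g <- function(l) sum((x[(1 + l):n] - m) * (x[1:(n - l)] - m)) / n
  vapply(0:max_lag, g, numeric(1)) / g(0)
}

# PACF via explicit Yule-Walker (Toeplitz) solves on the sample ACF
pacf_yw_oracle <- function(x, max_lag) {
  r <- acf_brute(x, max_lag)
  vapply(seq_len(max_lag), function(l) {
    R <- stats::toeplitz(r[1:l])
    solve(R, r[2:(l + 1)])[l]
  }, numeric(1))
}

# PACF variant: last coefficient of an explicit order-l OLS autoregression
pacf_ols_oracle <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  vapply(seq_len(max_lag), function(l) {
    y <- xc[(l + 1):n]
    X <- sapply(seq_len(l), function(j) xc[(l + 1 - j):(n - j)])
    cf <- coef(lm(y ~ as.matrix(X)))
    unname(cf[l + 1])
  }, numeric(1))
}

# a small simulated dataset and model frame shared by fitting tests; built
# once per test run
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_years = 2, clutches_per_year = 15, seed = 11)
      sim <- generate_dataset(cfg)
      cache <<- list(cfg = cfg, sim = sim,
                     frame = build_model_frame(sim$eggs, sim$temperature))
    }
    cache
  }
})

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(actual - expected)), tol))
}
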