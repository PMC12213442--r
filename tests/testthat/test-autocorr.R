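test_that("ACF equals the brute-force double loop on random series", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    L <- n - 2
    expect_close(clutch_acf(x, L), acf_brute(x, L), 1e-10)
  }
  # lag 0 is exactly 1 by definition
  x <- rnorm(20)
  expect_equal(unname(clutch_acf(x, 0)), 1)
  # alternating series has strongly negative lag-1 coefficient
  alt <- rep(c(1, -1), 3)
  expect_equal(unname(clutch_acf(alt, 1)[2]), acf_brute(alt, 1)[2])
  expect_lt(clutch_acf(alt, 1)[2], -0.5)
  expect_error(clutch_acf(rep(1, 10), 2), "constant")
  expect_error(clutch_acf(rnorm(4), 3), "too short")
})

test_that("Yule-Walker PACF matches an explicit Toeplitz solve and the lag-1 identity", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    L <- min(n - 2, 8)
    if (L < 1) next
    expect_close(clutch_pacf(x, L), pacf_yw_oracle(x, L), 1e-10)
    # lag-1 PACF is identically the lag-1 ACF
    expect_equal(unname(clutch_pacf(x, 1)[1]),
                 unname(clutch_acf(x, 1)[2]), tolerance = 1e-12)
  }
})

test_that("OLS PACF matches explicit least-squares autoregressions", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    x <- rnorm(n)
    L <- min(n %/% 3, 5)
    expect_close(clutch_pacf(x, L, method = "ols"),
                 pacf_ols_oracle(x, L), 1e-10)
  }
})

test_that("PACF of an AR(1) series cuts off after lag 1", {
  set.seed(45)
  rho <- 0.6
  x <- as.numeric(arima.sim(list(ar = rho), 5000))
  p <- clutch_pacf(x, 5)
  expect_lt(abs(p[1] - rho), 0.05)
  expect_true(all(abs(p[2:5]) < 2 / sqrt(5000) * 3))
})

test_that("white-noise band follows 2/sqrt(n) and is monotone", {
  expect_equal(whitenoise_band(4), 1)
  expect_equal(whitenoise_band(7.68), 2 / sqrt(7.68), tolerance = 1e-12)
  expect_equal(round(whitenoise_band(7.68), 5), 0.72169)
  n <- seq(2, 12, by = 0.5)
  expect_true(all(diff(whitenoise_band(n)) < 0))
  expect_error(whitenoise_band(0), "positive")
})

test_that("pooled lag-1 estimator matches cor.test on pooled pairs and excludes cross-clutch matches", {
  set.seed(46)
  clutch <- rep(sprintf("c%02d", 1:40), each = 6)
  pos <- rep(1:6, 40)
  r <- rnorm(240)
  est <- lag1_residual_rho(r, clutch, pos)
  # oracle: build the pairs by hand and use cor.test
  lead <- r[-1]; lag <- r[-240]
  keep <- clutch[-1] == clutch[-240]
  ct <- cor.test(lag[keep], lead[keep])
  expect_equal(est$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(est$t, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(est$df, unname(ct$parameter))
  expect_equal(est$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(est$n_pairs, sum(keep))
  expect_equal(est$n_pairs, 40 * 5)

  # white noise at scale: near-zero estimate
  clutch2 <- rep(seq_len(1100), each = 6)
  r2 <- rnorm(6600)
  est2 <- lag1_residual_rho(r2, clutch2, rep(1:6, 1100))
  expect_lt(abs(est2$rho), 0.05)

  # perfect alternation is flagged as degenerate
  alt <- rep(c(1, -1), 12)
  est3 <- lag1_residual_rho(alt, rep("a", 24), 1:24)
  expect_true(est3$flag_degenerate)
  expect_equal(est3$rho, -1)
  expect_error(lag1_residual_rho(rnorm(3), c("a", "b", "c"), c(1, 1, 1)),
               "pairs")
})

test_that("per-clutch lag table respects the size >= lag + 2 rule and aggregation flags", {
  set.seed(47)
  clutch <- c(rep("a", 4), rep("b", 8), rep("c", 3))
  pos <- c(1:4, 1:8, 1:3)
  r <- rnorm(15)
  tab <- residual_lag_coefs(r, clutch, pos, residual_type = "raw")
  # clutch a (4 eggs) contributes lags 1..2, b lags 1..6, c lag 1
  expect_equal(sort(unique(tab$lag[tab$clutch_id == "a" &
                                     tab$kind == "acf"])), 1:2)
  expect_equal(sort(unique(tab$lag[tab$clutch_id == "b" &
                                     tab$kind == "acf"])), 1:6)
  expect_equal(sort(unique(tab$lag[tab$clutch_id == "c" &
                                     tab$kind == "acf"])), 1)

  agg <- suppressWarnings(aggregate_lag_stats(tab, whitenoise_band(5)))
  expect_true(all(agg$n_clutches >= 2))
  # degenerate spread: identical coefficients across clutches
  fake <- data.frame(clutch_id = c("a", "b", "c"), lag = 1, kind = "acf",
                     residual_type = "raw", coefficient = 0.3)
  agg2 <- aggregate_lag_stats(fake, 0.5)
  expect_equal(agg2$mean, 0.3)
  expect_equal(agg2$sd, 0)
  expect_true(agg2$mean_within_band)
  # the mean +/- sd interval collapses to a point away from zero
  expect_false(agg2$sd_interval_overlaps_zero)
})

test_that("aggregation significance flags follow their definitions", {
  fake <- data.frame(clutch_id = rep(c("a", "b", "c", "d"), 2),
                     lag = rep(1:2, each = 4), kind = "acf",
                     residual_type = "raw",
                     coefficient = c(0.4, 0.5, 0.6, 0.5,
                                     -0.05, 0.05, 0.02, -0.02))
  agg <- aggregate_lag_stats(fake, 0.45)
  l1 <- agg[agg$lag == 1, ]
  l2 <- agg[agg$lag == 2, ]
  expect_false(l1$mean_within_band)          # mean 0.5 > 0.45
  expect_false(l1$sd_interval_overlaps_zero) # 0.5 +/- 0.08 excludes 0
  expect_true(l2$mean_within_band)
  expect_true(l2$sd_interval_overlaps_zero)
})

test_that("two-pass AR fit is deterministic and near-idempotent under a null process", {
  sim <- generate_dataset(synthetic_config(n_years = 2,
                                           clutches_per_year = 15,
                                           ar1_rho = 0, seed = 17))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  d <- model_design(include_order_by_clutch_size = FALSE,
                    include_temp_by_clutch_size = FALSE)
  a <- two_pass_ar_fit(d, fr)
  b <- two_pass_ar_fit(d, fr)
  expect_identical(a$rho$rho, b$rho$rho)
  expect_identical(coef(a$pass2$gam), coef(b$pass2$gam))
  # a third pass changes rho by less than 0.01
  est3 <- lag1_residual_rho(a$pass2$residuals_raw, a$pass2$frame$clutch_id,
                            a$pass2$frame$position)
  expect_lt(abs(est3$rho - a$rho$rho), 0.01)
  # with rho = 0 the standardized residuals equal the raw residuals
  expect_identical(a$pass1$residuals_std, a$pass1$residuals_raw)
})
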