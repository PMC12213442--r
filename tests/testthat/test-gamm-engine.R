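# fitting behaviour of the penalized-smooth engine against simple oracles

test_that("a purely linear signal is recovered at the OLS solution with edf near 1", {
  set.seed(101)
  sim <- generate_dataset(synthetic_config(
    n_years = 1, clutches_per_year = 30, between_clutch_cv = 0,
    between_year_sd = 0, residual_sd = 0, ar1_rho = 0,
    order_effect_points = cbind(c(-1.4, 0, 1.4), c(-0.05, 0, 0.05)),
    seed = 101))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  # volume is exactly linear in position_z within the anchors' line
  d <- model_design(include_clutch_size = FALSE,
                    include_temperature = FALSE,
                    include_order_by_clutch_size = FALSE,
                    include_temp_by_clutch_size = FALSE,
                    random_intercepts = character(0))
  # at exactly zero noise the REML scale estimate degenerates; the step
  # warning is expected and the fitted values are still the OLS solution
  fit <- suppressWarnings(fit_gamm(d, fr))
  ols <- lm(volume_scaled ~ position_z, data = fr)
  expect_close(fitted(fit), unname(fitted(ols)), 1e-5)

  # with ordinary noise the penalty shrinks the smooth to its linear null
  # space (REML smoothing selection is degenerate at exactly zero noise)
  sim2 <- generate_dataset(synthetic_config(
    n_years = 1, clutches_per_year = 30, between_clutch_cv = 0,
    between_year_sd = 0, residual_sd = 0.01, ar1_rho = 0,
    order_effect_points = cbind(c(-1.4, 0, 1.4), c(-0.05, 0, 0.05)),
    seed = 111))
  fr2 <- build_model_frame(sim2$eggs, sim2$temperature)
  fit2 <- fit_gamm(d, fr2)
  expect_lt(test_smooth(fit2, "order")$edf, 1.5)
  ols2 <- lm(volume_scaled ~ position_z, data = fr2)
  expect_close(fitted(fit2), unname(fitted(ols2)), 0.02)
})

test_that("pure clutch intercept structure is captured by the clutch random effect", {
  set.seed(102)
  sim <- generate_dataset(synthetic_config(
    n_years = 1, clutches_per_year = 40, between_clutch_cv = 0.08,
    between_year_sd = 0, residual_sd = 0.002, ar1_rho = 0,
    order_effect_points = cbind(c(-1, 0, 1), c(0, 0, 0)), seed = 102))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  # order smooth + clutch random intercept only, so no other term can
  # absorb between-clutch variance through shared seasonal structure
  d <- model_design(include_clutch_size = FALSE,
                    include_temperature = FALSE,
                    include_order_by_clutch_size = FALSE,
                    include_temp_by_clutch_size = FALSE,
                    random_intercepts = "clutch_id")
  part <- deviance_partition(d, fr, method = "both")
  cl_drop <- part$share_pct[part$term == "clutch_intercept" &
                              part$method == "drop_one"]
  cl_add <- part$share_pct[part$term == "clutch_intercept" &
                             part$method == "add_one"]
  expect_gte(cl_drop / attr(part, "full_dev_expl_pct"), 0.95)
  # one-way ANOVA oracle: between-clutch share of total sum of squares
  aov_fit <- aov(volume_scaled ~ clutch_id, data = fr)
  ss <- summary(aov_fit)[[1]][["Sum Sq"]]
  expect_lt(abs(cl_add / 100 - ss[1] / sum(ss)), 0.02)
})

test_that("the fitted order-effect curve recovers the generating quadratic", {
  sim <- generate_dataset(synthetic_config(seed = 103))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  fit <- fit_gamm(model_design(), fr)
  curve <- predict_order_effect(fit)
  truth_raw <- default_order_effect(curve$z)
  # the estimable quantity is the order effect centred on its egg-weighted
  # dataset mean; align means before comparing
  truth_pct <- 100 * (truth_raw - mean(default_order_effect(fr$position_z)))
  rmse <- sqrt(mean((curve$deviation_pct - truth_pct)^2))
  expect_lt(rmse, 0.5)
  # percent and mm3 axes are linked exactly by the dataset mean volume
  expect_close(curve$deviation_pct * attr(curve, "mean_volume_mm3") / 100,
               curve$deviation_mm3, 1e-8)
  expect_close(curve$volume_mm3 - attr(curve, "mean_volume_mm3"),
               curve$deviation_mm3, 1e-8)
})

test_that("AR-standardization follows the innovations transform and the rho = 0 identity", {
  r <- c(1, 2, 3, 4, -1, 0.5, 2)
  cl <- c("a", "a", "a", "a", "b", "b", "b")
  expect_identical(ar_standardize(r, cl, 0), r)
  rho <- 0.4
  e <- ar_standardize(r, cl, rho)
  expect_equal(e[1], r[1])
  expect_equal(e[5], r[5])
  expect_equal(e[2], (r[2] - rho * r[1]) / sqrt(1 - rho^2))
  expect_equal(e[6], (r[6] - rho * r[5]) / sqrt(1 - rho^2))
  # applied to a stationary AR(1) draw, it whitens the lag-1 correlation
  set.seed(104)
  n_cl <- 1500
  cl2 <- rep(seq_len(n_cl), each = 8)
  x <- as.numeric(replicate(n_cl, {
    v <- numeric(8); v[1] <- rnorm(1)
    for (t in 2:8) v[t] <- 0.35 * v[t - 1] + rnorm(1) * sqrt(1 - 0.35^2)
    v
  }))
  # before the transform the pooled pairs show the AR correlation
  raw_est <- lag1_residual_rho(x, cl2, rep(1:8, n_cl))
  expect_lt(abs(raw_est$rho - 0.35), 0.03)
  e2 <- ar_standardize(x, cl2, 0.35)
  est <- lag1_residual_rho(e2, cl2, rep(1:8, n_cl))
  expect_lt(abs(est$rho), 0.03)
})

test_that("deviance partition nests monotonically under add-one and respects single-term identity", {
  sim <- generate_dataset(synthetic_config(n_years = 1,
                                           clutches_per_year = 25,
                                           seed = 105))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  d <- model_design(include_order_by_clutch_size = FALSE,
                    include_temp_by_clutch_size = FALSE,
                    random_intercepts = "clutch_id")
  part <- deviance_partition(d, fr, method = "both")
  expect_true(all(part$share_pct >= -100 & part$share_pct <= 100))
  add <- part[part$method == "add_one", ]
  full <- attr(part, "full_dev_expl_pct")
  # each solitary term explains no more than the full model
  expect_true(all(add$share_pct <= full + 1e-6))

  # dropping every term at once leaves the intercept-only model, so the
  # grouped share equals the full explained deviance exactly
  d1 <- model_design(include_order_by_clutch_size = FALSE,
                     include_temp_by_clutch_size = FALSE,
                     random_intercepts = character(0))
  part1 <- deviance_partition(d1, fr, groups = list(
    everything = c("order", "clutch_size", "temperature")))
  expect_equal(part1$share_pct, attr(part1, "full_dev_expl_pct"),
               tolerance = 1e-10)
  expect_error(deviance_partition(d1, fr, groups = list(x = "nonexistent")),
               "unknown term")
})

test_that("concurvity is low for independent covariates and ~1 for duplicated ones", {
  set.seed(106)
  n <- 600
  fr <- data.frame(
    clutch_id = factor(rep(sprintf("c%02d", 1:100), each = 6)),
    year_f = factor(rep(1990, n)), year = 1990,
    position = rep(1:6, 100))
  fr$position_z <- zscore_within_clutch(fr$position, fr$clutch_id)
  fr$clutch_size_scaled <- rnorm(n)   # independent of position by design
  fr$tmin3_scaled <- rnorm(n)
  fr$volume_scaled <- rnorm(n)
  attr(fr, "scaling_record") <- list(
    volume_scaled = list(center = 0, scale = 1), mean_volume_mm3 = 1)
  d <- model_design(include_order_by_clutch_size = FALSE,
                    include_temp_by_clutch_size = FALSE,
                    random_intercepts = character(0))
  fit <- fit_gamm(d, fr)
  con <- concurvity_report(fit)
  obs <- con$summary$observed[con$summary$term %in%
                                c("clutch_size", "temperature")]
  expect_true(all(obs < 0.1))

  # a covariate that is constant within clutches is nearly spanned by the
  # clutch random intercept
  fr2 <- fr
  fr2$tmin3_scaled <- rep(rnorm(100), each = 6)
  d2 <- model_design(include_order_by_clutch_size = FALSE,
                     include_temp_by_clutch_size = FALSE,
                     random_intercepts = "clutch_id")
  fit2 <- fit_gamm(d2, fr2)
  con2 <- concurvity_report(fit2)
  expect_gt(con2$summary$observed[con2$summary$term == "temperature"], 0.7)
  expect_true(all(con2$summary$observed >= 0 & con2$summary$observed <= 1))
  expect_true(all(con2$pairwise_observed >= 0 & con2$pairwise_observed <= 1))
})

test_that("basis check reports k-index near 1 for white-noise residuals and flags saturation", {
  set.seed(107)
  sim <- generate_dataset(synthetic_config(n_years = 1,
                                           clutches_per_year = 130,
                                           ar1_rho = 0, seed = 107))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  d <- model_design(include_order_by_clutch_size = FALSE,
                    include_temp_by_clutch_size = FALSE)
  fit <- fit_gamm(d, fr)
  bc <- basis_check(fit)
  ki <- bc$k_index[bc$term %in% c("order", "temperature")]
  expect_true(all(abs(ki - 1) < 0.15))
  expect_false(any(bc$flag_raise_k[bc$term %in% c("order", "temperature")]))
})

test_that("null-effect fits give a flat order curve", {
  sim <- generate_dataset(synthetic_config(
    n_years = 1, clutches_per_year = 60,
    order_effect_points = cbind(c(-1, 0, 1), c(0, 0, 0)),
    ar1_rho = 0, seed = 108))
  fr <- build_model_frame(sim$eggs, sim$temperature)
  fit <- fit_gamm(model_design(), fr)
  curve <- predict_order_effect(fit)
  expect_true(all(abs(curve$deviation_pct) < 0.6))
})
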