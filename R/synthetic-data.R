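#' Default anchor points of the laying-order effect
#'
#' Three (z, relative effect) pairs defining the hump-shaped laying-order
#' effect on the within-clutch standard-score scale: first eggs slightly
#' below the mean, a peak just past mid-sequence, and a return to the mean
#' for the last eggs.
#'
#' @return A 3x2 matrix with columns `z` and `effect`.
#' @export
default_order_points <- function() {
  cbind(z = c(-1.4, 0.25, 1.4), effect = c(-0.025, 0.02, 0))
}

#' Coefficients of the quadratic through three order-effect anchor points
#'
#' Solves the 3x3 linear system for `a + b z + c z^2` through the supplied
#' points.
#'
#' @param points 3x2 matrix-like with columns (z, effect); z values must be
#'   strictly increasing.
#' @return Named numeric vector `c(a, b, c)`.
#' @export
order_effect_coefficients <- function(points = default_order_points()) {
  points <- as.matrix(points)
  if (nrow(points) != 3 || ncol(points) != 2)
    stop("order_effect_points must be three (z, effect) pairs")
  z <- points[, 1]
  if (any(diff(z) <= 0))
    stop("degenerate interpolation: z values must be strictly increasing")
  A <- cbind(1, z, z^2)
  setNames(as.numeric(solve(A, points[, 2])), c("a", "b", "c"))
}

#' Evaluate the laying-order effect quadratic
#'
#' Returns the relative (fraction of mean volume) laying-order effect at
#' within-clutch standard score `z`, i.e. the unique quadratic through the
#' configured anchor points.
#'
#' @param z Within-clutch standard score(s) of laying position.
#' @param points Anchor points, see [order_effect_coefficients()].
#' @return Numeric vector of relative effects.
#' @examples
#' default_order_effect(c(-1.4, 0.25, 1.4))
#' @export
default_order_effect <- function(z, points = default_order_points()) {
  cf <- order_effect_coefficients(points)
  cf[["a"]] + cf[["b"]] * z + cf[["c"]] * z^2
}

#' Discretised clutch-size distribution
#'
#' Normal(mean, sd) density evaluated on the integer support and
#' renormalised; used for the default clutch-size distribution (observed
#' mean 7.68, sd 0.67, range 4-10 eggs).
#'
#' @param mean,sd Target mean and sd of the underlying normal.
#' @param sizes Integer support (default 4:10).
#' @return Named probability vector over `sizes`, summing to 1.
#' @export
discretized_clutch_size_probs <- function(mean = 7.68, sd = 0.67,
                                          sizes = 4:10) {
  w <- dnorm(sizes, mean, sd)
  setNames(w / sum(w), sizes)
}

#' Configuration of the synthetic clutch generator
#'
#' Bundles every parameter of the generative model mirrored on the fitted
#' model: grand mean volume with multiplicative year, clutch, laying-order,
#' and temperature effects plus a within-clutch AR(1) residual; a seasonal
#' daily minimum-temperature series; and geometry back-solved from volume
#' under a sphericity profile that increases along the laying sequence.
#'
#' @param n_years Number of breeding seasons.
#' @param clutches_per_year Clutches initiated per season.
#' @param clutch_size_probs Probability vector over clutch sizes 4..10
#'   (named by size); must be non-negative and sum to 1.
#' @param grand_mean_volume Grand mean egg volume, mm^3.
#' @param between_clutch_cv Between-clutch sd as a fraction of the mean.
#' @param between_year_sd Between-year sd as a fraction of the mean.
#' @param order_effect_points Three (z, relative effect) anchor pairs of the
#'   laying-order quadratic; strictly increasing z.
#' @param temp_effect_slope Relative volume effect per scaled degree C of
#'   the 3-day formation-window mean minimum temperature (default 0).
#' @param order_temp_interaction_amp Relative amplitude of the z-by-scaled-
#'   temperature interaction (default 0).
#' @param ar1_rho Lag-1 autoregressive parameter of the within-clutch
#'   residual process, in (-1, 1); restarts independently at each clutch.
#' @param residual_sd Stationary sd of the residual process as a fraction
#'   of the mean.
#' @param season_start_doy Day of year on which the laying window opens.
#' @param laying_window_days Length of the window of first-egg dates.
#' @param temp_intercept Mean daily minimum temperature at the window
#'   start, degrees C.
#' @param temp_trend_per_day Linear seasonal trend in tmin, degrees C/day.
#' @param temp_noise_sd Day-to-day tmin noise sd, degrees C.
#' @param sphericity_mean,sphericity_slope Sphericity profile
#'   `mean + slope * z` used in the geometry back-solve.
#' @param volume_coef Volume-formula constants, see [compute_volume()].
#' @param seed Integer RNG seed recorded with the data.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_years = 5,
                             clutches_per_year = 29,
                             clutch_size_probs = discretized_clutch_size_probs(),
                             grand_mean_volume = 1506.24,
                             between_clutch_cv = 0.0769,
                             between_year_sd = 0.01,
                             order_effect_points = default_order_points(),
                             temp_effect_slope = 0,
                             order_temp_interaction_amp = 0,
                             ar1_rho = 0.19,
                             residual_sd = 0.02,
                             season_start_doy = 91,
                             laying_window_days = 45,
                             temp_intercept = 7,
                             temp_trend_per_day = 0.12,
                             temp_noise_sd = 1.5,
                             sphericity_mean = 0.755,
                             sphericity_slope = 0.012,
                             volume_coef = c(0.4673, 0.042),
                             seed = 1L) {
  cfg <- list(
    n_years = as.integer(n_years),
    clutches_per_year = as.integer(clutches_per_year),
    clutch_size_probs = clutch_size_probs,
    grand_mean_volume = grand_mean_volume,
    between_clutch_cv = between_clutch_cv,
    between_year_sd = between_year_sd,
    order_effect_points = as.matrix(order_effect_points),
    temp_effect_slope = temp_effect_slope,
    order_temp_interaction_amp = order_temp_interaction_amp,
    ar1_rho = ar1_rho,
    residual_sd = residual_sd,
    season_start_doy = as.integer(season_start_doy),
    laying_window_days = as.integer(laying_window_days),
    temp_intercept = temp_intercept,
    temp_trend_per_day = temp_trend_per_day,
    temp_noise_sd = temp_noise_sd,
    sphericity_mean = sphericity_mean,
    sphericity_slope = sphericity_slope,
    volume_coef = volume_coef,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  p <- cfg$clutch_size_probs
  if (is.null(names(p))) stop("clutch_size_probs must be named by size")
  if (any(p < 0)) stop("clutch_size_probs entries must be >= 0")
  if (abs(sum(p) - 1) > 1e-12) stop("clutch_size_probs must sum to 1")
  if (abs(cfg$ar1_rho) >= 1) stop("|ar1_rho| must be < 1")
  if (cfg$between_clutch_cv < 0 || cfg$residual_sd < 0 ||
      cfg$between_year_sd < 0)
    stop("dispersion parameters must be >= 0")
  z <- cfg$order_effect_points[, 1]
  if (nrow(cfg$order_effect_points) != 3 || any(diff(z) <= 0))
    stop("order_effect_points must have three strictly increasing z values")
  if (cfg$n_years < 1 || cfg$clutches_per_year < 1)
    stop("need at least one year and one clutch per year")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic clutch generator configuration\n")
  cat(sprintf("  %d year(s) x %d clutches; mean volume %.2f mm^3\n",
              x$n_years, x$clutches_per_year, x$grand_mean_volume))
  cat(sprintf("  between-clutch CV %.2f%%, between-year sd %.2f%%, AR(1) rho %.2f, residual sd %.2f%%\n",
              100 * x$between_clutch_cv, 100 * x$between_year_sd,
              x$ar1_rho, 100 * x$residual_sd))
  cat(sprintf("  order-effect anchors: f(%.2f)=%.3f, f(%.2f)=%.3f, f(%.2f)=%.3f\n",
              x$order_effect_points[1, 1], x$order_effect_points[1, 2],
              x$order_effect_points[2, 1], x$order_effect_points[2, 2],
              x$order_effect_points[3, 1], x$order_effect_points[3, 2]))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Stationary AR(1) draw: first value from the stationary distribution so the
# marginal variance is constant across laying positions.
ar1_series <- function(n, rho, sd) {
  e <- numeric(n)
  if (sd == 0) return(e)
  e[1] <- rnorm(1, 0, sd)
  if (n > 1)
    for (t in 2:n) e[t] <- rho * e[t - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
  e
}

within_clutch_z <- function(n) {
  pos <- seq_len(n)
  (pos - mean(pos)) / sd(pos)
}

#' Generate a synthetic egg and temperature dataset
#'
#' Simulates the full study structure: per year, clutches start on a random
#' date within the laying window and lay one egg per calendar day; egg
#' volume at within-clutch standard score z is
#' `mu * (1 + b_year + b_clutch + f(z) + beta_T * Tsc + gamma * z * Tsc) + eps`
#' with `f` the order-effect quadratic, `Tsc` the dataset-scaled 3-day
#' formation-window mean minimum temperature, and `eps` a within-clutch
#' AR(1) process restarting at each clutch. Length and breadth are
#' back-solved from volume under a sphericity profile increasing along the
#' sequence, so [compute_volume()] recovers the simulated volume exactly.
#'
#' The RNG seed is taken from `config$seed`; the same configuration always
#' yields byte-identical tables.
#'
#' @param config A [synthetic_config()] object.
#' @return An object of class `"egg_simulation"`: a list with `eggs`
#'   (clutch_id, year, lay_date, position, length_mm, breadth_mm),
#'   `temperature` (date, tmin_c) and `truth` (every latent effect: year
#'   and clutch intercepts, per-egg order effects, residual process,
#'   scaled temperatures, quadratic coefficients, config echo).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  mu <- config$grand_mean_volume
  sizes_support <- as.integer(names(config$clutch_size_probs))
  qcoef <- order_effect_coefficients(config$order_effect_points)
  base_year <- 1990L

  years <- base_year + seq_len(config$n_years) - 1L
  b_year <- setNames(rnorm(config$n_years, 0, config$between_year_sd), years)

  # temperature series per year, covering all formation windows
  first_doy_min <- config$season_start_doy
  last_doy <- config$season_start_doy + config$laying_window_days - 1L +
    max(sizes_support) + 3L
  temperature <- do.call(rbind, lapply(years, function(y) {
    doy <- (first_doy_min - 4L):last_doy
    tmin <- config$temp_intercept +
      config$temp_trend_per_day * (doy - config$season_start_doy) +
      rnorm(length(doy), 0, config$temp_noise_sd)
    data.frame(date = as.Date(paste0(y, "-01-01")) + doy - 1L,
               tmin_c = round(tmin, 6))
  }))

  clutch_rows <- list()
  egg_rows <- list()
  k <- 0L
  for (iy in seq_along(years)) {
    y <- years[iy]
    for (ic in seq_len(config$clutches_per_year)) {
      k <- k + 1L
      id <- sprintf("c%03d", k)
      n <- sample(sizes_support, 1L, prob = config$clutch_size_probs)
      start_doy <- config$season_start_doy +
        sample.int(config$laying_window_days, 1L) - 1L
      b_clutch <- rnorm(1, 0, config$between_clutch_cv)
      z <- within_clutch_z(n)
      eps <- ar1_series(n, config$ar1_rho, config$residual_sd * mu)
      clutch_rows[[k]] <- data.frame(clutch_id = id, year = y,
                                     clutch_size = n, first_doy = start_doy,
                                     b_year = b_year[[as.character(y)]],
                                     b_clutch = b_clutch)
      egg_rows[[k]] <- data.frame(
        clutch_id = id, year = y,
        lay_date = as.Date(paste0(y, "-01-01")) + start_doy - 1L +
          seq_len(n) - 1L,
        position = seq_len(n), z = z,
        f_order = default_order_effect(z, config$order_effect_points),
        eps = eps)
    }
  }
  clutches <- do.call(rbind, clutch_rows)
  eggs <- do.call(rbind, egg_rows)

  tmin3 <- mean_tmin_window(temperature, eggs$lay_date)
  tmin3_scaled <- if (sd(tmin3) > 0) (tmin3 - mean(tmin3)) / sd(tmin3)
                  else rep(0, length(tmin3))

  idx <- match(eggs$clutch_id, clutches$clutch_id)
  rel <- 1 + clutches$b_year[idx] + clutches$b_clutch[idx] + eggs$f_order +
    config$temp_effect_slope * tmin3_scaled +
    config$order_temp_interaction_amp * eggs$z * tmin3_scaled
  volume <- mu * rel + eggs$eps
  if (any(volume <= config$volume_coef[2]))
    stop("invalid config: generated volumes too small for the geometry back-solve")

  sph <- config$sphericity_mean + config$sphericity_slope * eggs$z
  geom <- back_solve_geometry(volume, sph, config$volume_coef)

  out_eggs <- data.frame(
    clutch_id = eggs$clutch_id, year = eggs$year,
    lay_date = eggs$lay_date, position = eggs$position,
    length_mm = geom$length_mm, breadth_mm = geom$breadth_mm)

  truth <- list(
    config = config,
    order_coefficients = qcoef,
    year_effects = as.list(b_year),
    clutches = clutches,
    eggs = data.frame(clutch_id = eggs$clutch_id, position = eggs$position,
                      z = eggs$z, f_order = eggs$f_order, eps = eggs$eps,
                      tmin3_c = tmin3, tmin3_scaled = tmin3_scaled,
                      volume_mm3 = volume, sphericity = sph))
  structure(list(eggs = out_eggs, temperature = temperature, truth = truth),
            class = "egg_simulation")
}

#' @export
print.egg_simulation <- function(x, ...) {
  cat(sprintf("Synthetic egg dataset: %d eggs in %d clutches over %d year(s)\n",
              nrow(x$eggs), length(unique(x$eggs$clutch_id)),
              length(unique(x$eggs$year))))
  cat(sprintf("  mean volume %.2f mm^3 (truth), seed %d\n",
              mean(x$truth$eggs$volume_mm3), x$truth$config$seed))
  invisible(x)
}

#' Write a simulated dataset to CSV/JSON files
#'
#' Writes `eggs.csv`, `temperature.csv` and `truth.json` into `dir`.
#'
#' @param sim An [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "egg_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(eggs = file.path(dir, "eggs.csv"),
             temperature = file.path(dir, "temperature.csv"),
             truth = file.path(dir, "truth.json"))
  eggs <- sim$eggs
  eggs$lay_date <- format(eggs$lay_date, "%Y-%m-%d")
  temp <- sim$temperature
  temp$date <- format(temp$date, "%Y-%m-%d")
  write.csv(eggs, paths["eggs"], row.names = FALSE)
  write.csv(temp, paths["temperature"], row.names = FALSE)
  tr <- sim$truth
  tr$config <- unclass(tr$config)
  tr$config$order_effect_points <- as.data.frame(tr$config$order_effect_points)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(paths)
}

#' Analytic variance shares implied by a generator configuration
#'
#' Enumerates the clutch-size distribution to compute the population
#' variance contributed by each model component on the relative-volume
#' scale, the implied intraclass correlation of clutch identity, and the
#' egg-weighted mean of the laying-order effect (the part absorbed by the
#' model intercept).
#'
#' @param config A [synthetic_config()] object.
#' @return A list with `components` (named variances), `shares`
#'   (fractions of total), `icc_clutch` and `mean_order_effect`.
#' @export
analytic_variance_shares <- function(config = synthetic_config()) {
  sizes <- as.integer(names(config$clutch_size_probs))
  p <- as.numeric(config$clutch_size_probs)
  w <- p * sizes / sum(p * sizes)  # probability an egg is in a size-n clutch
  f1 <- f2 <- z2 <- 0
  for (i in seq_along(sizes)) {
    z <- within_clutch_z(sizes[i])
    f <- default_order_effect(z, config$order_effect_points)
    f1 <- f1 + w[i] * mean(f)
    f2 <- f2 + w[i] * mean(f^2)
    z2 <- z2 + w[i] * mean(z^2)
  }
  comp <- c(
    clutch = config$between_clutch_cv^2,
    year = config$between_year_sd^2,
    order = f2 - f1^2,
    temperature = config$temp_effect_slope^2,
    order_x_temp = config$order_temp_interaction_amp^2 * z2,
    residual = config$residual_sd^2)
  list(components = comp, shares = comp / sum(comp),
       icc_clutch = comp[["clutch"]] / sum(comp),
       mean_order_effect = f1)
}
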