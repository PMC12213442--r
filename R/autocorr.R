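#' Pooled within-clutch lag-1 residual correlation
#'
#' Builds all consecutive within-clutch residual pairs (positions t-1, t),
#' pools them across clutches (matches across different clutches are
#' excluded), and returns the plain Pearson correlation of the pooled
#' pairs with `t = r * sqrt(df) / sqrt(1 - r^2)`, `df = n_pairs - 2`, and
#' a two-sided p-value. This is the two-pass procedure's first-pass
#' estimate of the AR(1) parameter.
#'
#' @param residuals Numeric residual vector.
#' @param clutch_id Clutch identifier aligned with `residuals`.
#' @param position Optional laying positions; when supplied, rows are
#'   ordered by position within clutch and only pairs one position apart
#'   are used.
#' @return List of class `"lag1_rho"`: `rho`, `t`, `df`, `p_value`,
#'   `n_pairs`, and `flag_degenerate` when |rho| is at the boundary.
#' @export
lag1_residual_rho <- function(residuals, clutch_id, position = NULL) {
  stopifnot(length(residuals) == length(clutch_id))
  if (!is.null(position)) {
    o <- order(as.character(clutch_id), position)
    residuals <- residuals[o]
    clutch_id <- clutch_id[o]
    position <- position[o]
  }
  same <- as.character(clutch_id[-length(clutch_id)]) ==
    as.character(clutch_id[-1])
  if (!is.null(position))
    same <- same & diff(position) == 1
  i <- which(same)
  if (length(i) < 3) stop("fewer than 3 within-clutch pairs")
  x <- residuals[i]
  y <- residuals[i + 1]
  r <- cor(x, y)
  df <- length(i) - 2
  degenerate <- abs(r) >= 1 - 1e-12
  tt <- if (degenerate) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  structure(list(rho = r, t = tt, df = df,
                 p_value = 2 * pt(-abs(tt), df),
                 n_pairs = length(i), flag_degenerate = degenerate),
            class = "lag1_rho")
}

#' @export
print.lag1_rho <- function(x, ...) {
  cat(sprintf(
    "Pooled within-clutch lag-1 correlation: r = %.3f (t = %.2f, df = %d, p = %.3g, %d pairs)\n",
    x$rho, x$t, x$df, x$p_value, x$n_pairs))
  invisible(x)
}

#' Two-pass AR(1) fit
#'
#' Pass 1 fits the design without an autocorrelation structure; the pooled
#' within-clutch lag-1 correlation of its residuals estimates the AR(1)
#' parameter; pass 2 refits with that parameter fixed in the residual
#' covariance. Both passes and the estimate are retained. The procedure is
#' deterministic: the same frame always yields identical output.
#'
#' @param design A [model_design()].
#' @param frame A [build_model_frame()] result.
#' @return List of class `"two_pass_fit"`: `pass1`, `pass2` (both
#'   [fit_gamm()] objects) and `rho` (a `"lag1_rho"`).
#' @export
two_pass_ar_fit <- function(design, frame) {
  pass1 <- fit_gamm(design, frame, rho = 0)
  est <- lag1_residual_rho(pass1$residuals_raw, pass1$frame$clutch_id,
                           pass1$frame$position)
  pass2 <- fit_gamm(design, frame, rho = est$rho)
  structure(list(pass1 = pass1, pass2 = pass2, rho = est),
            class = "two_pass_fit")
}

#' @export
print.two_pass_fit <- function(x, ...) {
  cat("Two-pass AR(1) egg GAMM\n")
  cat(sprintf("  pass-1 residual lag-1 rho = %.3f (t = %.2f, df = %d)\n",
              x$rho$rho, x$rho$t, x$rho$df))
  cat(sprintf("  pass-2 deviance explained: %.1f%%\n", 100 * x$pass2$dev_expl))
  invisible(x)
}

#' Sample autocorrelation function of one clutch series
#'
#' Standard sample ACF: covariances centred on the series (or a supplied
#' global) mean and normalised by lag 0, so the lag-0 coefficient is
#' exactly 1.
#'
#' @param series Numeric series (residuals of one clutch in laying order).
#' @param max_lag Largest lag; default `length(series) - 2`.
#' @param center `"series"` (each series by its own mean, default) or
#'   `"global"` (by `global_mean`).
#' @param global_mean Mean used when `center = "global"`.
#' @return Named numeric vector of coefficients for lags 0..max_lag.
#' @export
clutch_acf <- function(series, max_lag = NULL, center = c("series", "global"),
                       global_mean = 0) {
  center <- match.arg(center)
  if (is.null(max_lag)) max_lag <- length(series) - 2L
  if (length(series) < max_lag + 2)
    stop("series too short for lag ", max_lag)
  if (max_lag < 0) stop("max_lag must be >= 0")
  if (sd(series) == 0) stop("constant series: ACF undefined")
  a <- if (center == "series")
    acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  else
    acf(series - global_mean, lag.max = max_lag, plot = FALSE,
        demean = FALSE)
  setNames(as.numeric(a$acf), 0:max_lag)
}

#' Sample partial autocorrelation function of one clutch series
#'
#' The PACF at lag l is the lag-l autoregressive coefficient of an
#' order-l model. `"yule_walker"` (default) obtains it from the sample ACF
#' via the Durbin-Levinson recursion — this is what `pacf()` computes and
#' makes the lag-1 PACF identical to the lag-1 ACF. `"ols"` instead takes
#' the last coefficient of an explicit order-l least-squares
#' autoregression; at short series lengths the two differ at the edges.
#' Singular OLS systems yield `NA` coefficients.
#'
#' @inheritParams clutch_acf
#' @param method `"yule_walker"` or `"ols"`.
#' @return Named numeric vector of coefficients for lags 1..max_lag.
#' @export
clutch_pacf <- function(series, max_lag = NULL,
                        method = c("yule_walker", "ols"),
                        center = c("series", "global"), global_mean = 0) {
  method <- match.arg(method)
  center <- match.arg(center)
  if (is.null(max_lag)) max_lag <- length(series) - 2L
  if (length(series) < max_lag + 2)
    stop("series too short for lag ", max_lag)
  if (max_lag < 1) stop("max_lag must be >= 1")
  if (sd(series) == 0) stop("constant series: PACF undefined")
  x <- if (center == "series") series - mean(series)
       else series - global_mean
  if (method == "yule_walker") {
    p <- acf(x, lag.max = max_lag, plot = FALSE, demean = FALSE,
             type = "partial")
    return(setNames(as.numeric(p$acf), 1:max_lag))
  }
  out <- rep(NA_real_, max_lag)
  n <- length(x)
  for (l in seq_len(max_lag)) {
    y <- x[(l + 1):n]
    X <- sapply(seq_len(l), function(j) x[(l + 1 - j):(n - j)])
    X <- matrix(X, ncol = l)
    fit <- tryCatch(lm.fit(cbind(1, X), y), error = function(e) NULL)
    cf <- if (is.null(fit)) NA_real_ else fit$coefficients[l + 1]
    out[l] <- if (is.null(fit) || is.na(cf)) NA_real_ else cf
  }
  setNames(out, 1:max_lag)
}

#' White-noise band half-width
#'
#' The non-significant interval for the lag correlations of a white-noise
#' series of length equal to the mean clutch size: half-width
#' `2 / sqrt(mean_clutch_size)`.
#'
#' @param mean_clutch_size Mean clutch size (eggs per clutch), > 0.
#' @return The band half-width.
#' @examples
#' whitenoise_band(4)     # 1
#' whitenoise_band(7.68)
#' @export
whitenoise_band <- function(mean_clutch_size) {
  if (!is.numeric(mean_clutch_size) || any(mean_clutch_size <= 0))
    stop("mean clutch size must be positive")
  2 / sqrt(mean_clutch_size)
}

#' Per-clutch lag coefficients of model residuals
#'
#' Computes the ACF and/or PACF of the residual series of every clutch,
#' in laying order. A clutch contributes at lag l only if it has at least
#' l + 2 eggs; lags are within-clutch position offsets, equal to days
#' under one-egg-per-day laying.
#'
#' @param residuals Numeric residual vector.
#' @param clutch_id Clutch identifier aligned with `residuals`.
#' @param position Laying positions (used to order within clutch).
#' @param kind Character subset of `c("acf", "pacf")`.
#' @param residual_type Label recorded in the output (`"raw"` or
#'   `"standardized"`).
#' @param max_lag Largest lag; default max clutch size minus 2.
#' @param center,global_mean See [clutch_acf()].
#' @param pacf_method See [clutch_pacf()].
#' @return Tidy data.frame: `clutch_id`, `lag`, `kind`, `residual_type`,
#'   `coefficient`. Constant or degenerate clutch series are skipped.
#' @export
residual_lag_coefs <- function(residuals, clutch_id, position,
                               kind = c("acf", "pacf"),
                               residual_type = "raw", max_lag = NULL,
                               center = c("series", "global"),
                               global_mean = NULL,
                               pacf_method = c("yule_walker", "ols")) {
  kind <- match.arg(kind, several.ok = TRUE)
  center <- match.arg(center)
  pacf_method <- match.arg(pacf_method)
  o <- order(as.character(clutch_id), position)
  residuals <- residuals[o]
  clutch_id <- as.character(clutch_id)[o]
  sizes <- table(clutch_id)
  if (is.null(max_lag)) max_lag <- max(sizes) - 2L
  if (is.null(global_mean)) global_mean <- mean(residuals)
  rows <- list()
  for (id in names(sizes)) {
    x <- residuals[clutch_id == id]
    L <- min(max_lag, length(x) - 2L)
    if (L < 1 || sd(x) == 0) next
    if ("acf" %in% kind) {
      cc <- clutch_acf(x, L, center = center, global_mean = global_mean)
      rows[[length(rows) + 1]] <- data.frame(
        clutch_id = id, lag = 1:L, kind = "acf",
        residual_type = residual_type, coefficient = as.numeric(cc[-1]))
    }
    if ("pacf" %in% kind) {
      cc <- clutch_pacf(x, L, method = pacf_method, center = center,
                        global_mean = global_mean)
      rows[[length(rows) + 1]] <- data.frame(
        clutch_id = id, lag = 1:L, kind = "pacf",
        residual_type = residual_type, coefficient = as.numeric(cc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-clutch lag coefficients
#'
#' Per lag (and kind and residual type): the mean and standard deviation
#' of the per-clutch coefficients, the white-noise band, and two
#' significance flags — whether the mean lies within the band, and whether
#' the mean +/- sd interval overlaps zero. Lags with fewer than two
#' contributing clutches are dropped with a warning.
#'
#' @param coefs A [residual_lag_coefs()] result (or compatible
#'   data.frame).
#' @param band_halfwidth White-noise band half-width, see
#'   [whitenoise_band()].
#' @return Data.frame: `kind`, `residual_type`, `lag`, `n_clutches`,
#'   `mean`, `sd`, `band_halfwidth`, `mean_within_band`,
#'   `sd_interval_overlaps_zero`.
#' @export
aggregate_lag_stats <- function(coefs, band_halfwidth) {
  stopifnot(band_halfwidth > 0)
  coefs <- coefs[!is.na(coefs$coefficient), ]
  key <- interaction(coefs$kind, coefs$residual_type, coefs$lag, drop = TRUE)
  rows <- lapply(split(coefs, key), function(g) {
    data.frame(kind = g$kind[1], residual_type = g$residual_type[1],
               lag = g$lag[1], n_clutches = nrow(g),
               mean = mean(g$coefficient), sd = sd(g$coefficient))
  })
  out <- do.call(rbind, rows)
  drop <- out$n_clutches < 2
  if (any(drop)) {
    warning("dropping lag(s) with fewer than 2 clutches: ",
            paste(unique(out$lag[drop]), collapse = ", "))
    out <- out[!drop, ]
  }
  out <- out[order(out$kind, out$residual_type, out$lag), ]
  out$band_halfwidth <- band_halfwidth
  out$mean_within_band <- abs(out$mean) <= band_halfwidth
  out$sd_interval_overlaps_zero <- (out$mean - out$sd) <= 0 &
    0 <= (out$mean + out$sd)
  rownames(out) <- NULL
  out
}
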