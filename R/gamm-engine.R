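#' Declarative specification of the hierarchical GAMM
#'
#' Describes the smooth terms of the egg model: cubic regression spline
#' main effects of laying position (within-clutch standard score), clutch
#' size and formation-window temperature; isotropic thin plate interaction
#' surfaces (variables share the standard-deviation unit, so an isotropic
#' basis is appropriate); random intercepts for clutch identity and year;
#' optionally an order-by-temperature surface and a per-clutch factor
#' smooth of laying position (the random-slope analogue, off by default).
#' Basis dimensions are clipped to the number of unique covariate values at
#' fit time.
#'
#' @param response Response column of the model frame.
#' @param k_position,k_clutch_size,k_temperature Basis dimensions of the
#'   univariate cubic regression splines.
#' @param k_interaction Basis dimension cap of the bivariate thin plate
#'   terms.
#' @param include_clutch_size,include_temperature Include the clutch-size
#'   and temperature main-effect smooths (both default on; the laying-order
#'   smooth is always present).
#' @param include_order_by_clutch_size,include_temp_by_clutch_size,include_order_by_temp
#'   Which interaction surfaces to include. The first two are the default
#'   set; the order-by-temperature surface is available for sensitivity
#'   analyses.
#' @param random_intercepts Character subset of `c("clutch_id", "year")`.
#' @param factor_smooth Include the per-clutch factor smooth of position?
#' @param k_factor_smooth Basis dimension of the factor smooth.
#' @param ar1_rho `"none"` or a fixed AR(1) parameter for the within-clutch
#'   residual covariance (independent across clutches).
#' @return An object of class `"model_design"`.
#' @export
model_design <- function(response = "volume_scaled",
                         k_position = 5, k_clutch_size = 5,
                         k_temperature = 8, k_interaction = 25,
                         include_clutch_size = TRUE,
                         include_temperature = TRUE,
                         include_order_by_clutch_size = TRUE,
                         include_temp_by_clutch_size = TRUE,
                         include_order_by_temp = FALSE,
                         random_intercepts = c("clutch_id", "year"),
                         factor_smooth = FALSE, k_factor_smooth = 5,
                         ar1_rho = "none") {
  if (!identical(ar1_rho, "none")) {
    stopifnot(is.numeric(ar1_rho), abs(ar1_rho) < 1)
  }
  stopifnot(all(random_intercepts %in% c("clutch_id", "year")))
  if (any(c(k_position, k_clutch_size, k_temperature) < 3))
    stop("univariate basis dimension k must be >= 3")
  structure(list(
    response = response,
    k = list(position = k_position, clutch_size = k_clutch_size,
             temperature = k_temperature, interaction = k_interaction,
             factor_smooth = k_factor_smooth),
    include_clutch_size = include_clutch_size,
    include_temperature = include_temperature,
    include_order_by_clutch_size = include_order_by_clutch_size,
    include_temp_by_clutch_size = include_temp_by_clutch_size,
    include_order_by_temp = include_order_by_temp,
    random_intercepts = random_intercepts,
    factor_smooth = factor_smooth,
    ar1_rho = ar1_rho), class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat("Egg GAMM design:", x$response, "~\n")
  for (t in design_terms(x)) cat("  +", t, "\n")
  cat("AR(1) rho:", if (identical(x$ar1_rho, "none")) "none"
      else format(x$ar1_rho), "| criterion: REML\n")
  invisible(x)
}

# Named list of formula chunks, one per droppable model term. Univariate
# terms use cubic regression splines, bivariate terms isotropic thin plate
# splines, random intercepts an identity ("re") penalty.
design_terms <- function(design, frame = NULL) {
  k <- design$k
  if (!is.null(frame)) {
    clip <- function(kk, v) max(3, min(kk, length(unique(v))))
    k$position <- clip(k$position, frame$position_z)
    k$clutch_size <- clip(k$clutch_size, frame$clutch_size_scaled)
    k$temperature <- clip(k$temperature, frame$tmin3_scaled)
    n_pairs <- nrow(unique(frame[, c("position_z", "clutch_size_scaled")]))
    k$interaction <- max(3, min(k$interaction, n_pairs))
  }
  terms <- list(
    order = sprintf("s(position_z, bs = 'cr', k = %d)", k$position))
  if (isTRUE(design$include_clutch_size) || is.null(design$include_clutch_size))
    terms$clutch_size <- sprintf("s(clutch_size_scaled, bs = 'cr', k = %d)",
                                 k$clutch_size)
  if (isTRUE(design$include_temperature) || is.null(design$include_temperature))
    terms$temperature <- sprintf("s(tmin3_scaled, bs = 'cr', k = %d)",
                                 k$temperature)
  if (design$include_order_by_clutch_size)
    terms$order_x_clutch_size <-
      sprintf("s(position_z, clutch_size_scaled, bs = 'tp', k = %d)",
              k$interaction)
  if (design$include_temp_by_clutch_size)
    terms$temp_x_clutch_size <-
      sprintf("s(tmin3_scaled, clutch_size_scaled, bs = 'tp', k = %d)",
              k$interaction)
  if (design$include_order_by_temp)
    terms$order_x_temp <-
      sprintf("s(position_z, tmin3_scaled, bs = 'tp', k = %d)",
              k$interaction)
  # a random intercept needs at least two factor levels to be estimable
  if ("clutch_id" %in% design$random_intercepts &&
      (is.null(frame) || length(unique(frame$clutch_id)) > 1))
    terms$clutch_intercept <- "s(clutch_id, bs = 're')"
  if ("year" %in% design$random_intercepts &&
      (is.null(frame) || length(unique(frame$year_f)) > 1))
    terms$year_intercept <- "s(year_f, bs = 're')"
  if (design$factor_smooth)
    terms$order_by_clutch_fs <-
      sprintf("s(position_z, clutch_id, bs = 'fs', k = %d)",
              k$factor_smooth)
  terms
}

design_formula <- function(design, frame, drop = NULL, only = NULL) {
  terms <- design_terms(design, frame)
  if (!is.null(drop)) {
    if (!all(drop %in% names(terms))) stop("unknown term(s): ",
                                           paste(setdiff(drop, names(terms)),
                                                 collapse = ", "))
    terms <- terms[setdiff(names(terms), drop)]
  }
  if (!is.null(only)) {
    if (!all(only %in% names(terms))) stop("unknown term(s): ",
                                           paste(setdiff(only, names(terms)),
                                                 collapse = ", "))
    terms <- terms[only]
  }
  rhs <- if (length(terms)) paste(unlist(terms), collapse = " + ") else "1"
  stats::as.formula(paste(design$response, "~", rhs))
}

#' Fit the hierarchical penalized-smooth model
#'
#' Fits the design by penalized least squares with smoothing parameters
#' chosen by restricted maximum likelihood (via [mgcv::gam()]), Gaussian
#' response with identity link. Random intercepts are penalized
#' identity-penalty terms, equivalent to i.i.d. Gaussian effects. When an
#' AR(1) parameter is set, the working residual covariance is block AR(1)
#' within clutches and independent across clutches (the process restarts
#' at each clutch's first egg): the response and model bases are passed
#' through the exact AR(1) innovations transform before REML fitting,
#' i.e. generalized least squares under the block AR(1) covariance. Rows
#' are sorted by year, clutch and position before fitting.
#'
#' AR-standardized residuals follow the innovations transform
#' `e_1 = r_1`, `e_t = (r_t - rho * r_(t-1)) / sqrt(1 - rho^2)` within each
#' clutch; with `rho = 0` they equal the raw residuals exactly.
#'
#' @param design A [model_design()].
#' @param frame A [build_model_frame()] result covering all design
#'   covariates.
#' @param rho Optional AR(1) parameter overriding `design$ar1_rho`.
#' @return An object of class `"egg_gamm"`: the mgcv fit plus the design,
#'   the rho used, raw and AR-standardized residuals (in frame order),
#'   per-term effective degrees of freedom and Wald-like tests, deviance
#'   accounting and the frame's scaling record.
#' @export
fit_gamm <- function(design, frame, rho = NULL) {
  stopifnot(inherits(design, "model_design"))
  if (is.null(rho))
    rho <- if (identical(design$ar1_rho, "none")) 0 else design$ar1_rho
  frame <- frame[order(frame$year, as.character(frame$clutch_id),
                       frame$position), ]
  ar_start <- !duplicated(frame$clutch_id)
  form <- design_formula(design, frame)
  environment(form) <- environment()
  fit <- fit_penalized(form, frame, rho, ar_start, design$response)
  sm <- summary(fit)
  fitted_orig <- as.numeric(predict(fit, newdata = frame))
  raw <- as.numeric(frame[[design$response]]) - fitted_orig
  std <- ar_standardize(raw, frame$clutch_id, rho)
  structure(list(
    gam = fit, design = design, rho = rho,
    frame = frame, ar_start = ar_start,
    fitted_values = fitted_orig,
    residuals_raw = raw, residuals_std = std,
    s_table = sm$s.table,
    dev_expl = as.numeric(sm$dev.expl),
    deviance = as.numeric(fit$deviance),
    null_deviance = as.numeric(fit$null.deviance),
    reml = as.numeric(fit$gcv.ubre),
    edf_total = sum(fit$edf),
    n = nrow(frame),
    scaling_record = attr(frame, "scaling_record")),
    class = "egg_gamm")
}

# Penalized-smooth fit with optional AR(1) working covariance. The model is
# set up on the original data; when rho != 0 the response and every basis
# column are passed through the exact AR(1) innovations (whitening)
# transform within clutches before REML fitting, which is the generalized
# least squares fit under a block AR(1) residual covariance restarting at
# each clutch.
fit_penalized <- function(form, frame, rho, ar_start, response) {
  if (rho == 0)
    return(mgcv::gam(form, data = frame, method = "REML"))
  G <- mgcv::gam(form, data = frame, method = "REML", fit = FALSE)
  G$X <- ar_whiten(G$X, ar_start, rho)
  yw <- as.numeric(ar_whiten(matrix(as.numeric(frame[[response]])),
                             ar_start, rho))
  G$y <- yw
  G$mf[[response]] <- yw
  mgcv::gam(G = G, method = "REML")
}

# row-wise AR(1) innovations transform of a matrix, restarting where
# `first` is TRUE
ar_whiten <- function(M, first, rho) {
  M <- as.matrix(M)
  lag <- rbind(0, M[-nrow(M), , drop = FALSE])
  out <- (M - rho * lag) / sqrt(1 - rho^2)
  out[first, ] <- M[first, , drop = FALSE]
  out
}

#' @export
print.egg_gamm <- function(x, ...) {
  cat("Hierarchical egg GAMM (REML)\n")
  cat(sprintf("  n = %d eggs, %d clutches; AR(1) rho = %.3f\n",
              x$n, nlevels(x$frame$clutch_id), x$rho))
  cat(sprintf("  deviance explained: %.1f%%; total edf %.1f\n",
              100 * x$dev_expl, x$edf_total))
  print(round(x$s_table, 4))
  invisible(x)
}

#' @export
residuals.egg_gamm <- function(object, type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  if (type == "raw") object$residuals_raw else object$residuals_std
}

#' @export
fitted.egg_gamm <- function(object, ...) object$fitted_values

#' AR(1)-standardize residuals within clutches
#'
#' Applies the innovations transform `e_1 = r_1`,
#' `e_t = (r_t - rho * r_(t-1)) / sqrt(1 - rho^2)` within each clutch,
#' assuming rows are ordered by position within clutch.
#'
#' @param residuals Numeric residual vector.
#' @param clutch_id Clutch identifier aligned with `residuals`.
#' @param rho AR(1) parameter in (-1, 1).
#' @return Numeric vector of standardized residuals.
#' @export
ar_standardize <- function(residuals, clutch_id, rho) {
  stopifnot(abs(rho) < 1)
  if (rho == 0) return(residuals)
  first <- !duplicated(clutch_id)
  out <- c(0, residuals[-length(residuals)])
  out <- (residuals - rho * out) / sqrt(1 - rho^2)
  out[first] <- residuals[first]
  out
}

#' Back-transform fitted values to mm^3
#'
#' @param fit An [fit_gamm()] result with a volume-scaled response.
#' @return Numeric vector of fitted volumes in mm^3, in frame order.
#' @export
fitted_volume <- function(fit) {
  rec <- fit$scaling_record
  unscale(fitted(fit), rec$volume_scaled$center, rec$volume_scaled$scale)
}
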