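# canonical term name -> mgcv smooth label
term_labels <- function(design, frame = NULL) {
  lab <- c(order = "s(position_z)",
           clutch_size = "s(clutch_size_scaled)",
           temperature = "s(tmin3_scaled)",
           order_x_clutch_size = "s(position_z,clutch_size_scaled)",
           temp_x_clutch_size = "s(tmin3_scaled,clutch_size_scaled)",
           order_x_temp = "s(position_z,tmin3_scaled)",
           clutch_intercept = "s(clutch_id)",
           year_intercept = "s(year_f)",
           order_by_clutch_fs = "s(position_z,clutch_id)")
  lab[names(design_terms(design, frame))]
}

#' Wald-like tests of smooth terms
#'
#' For each smooth term, the test of the null hypothesis that the smooth is
#' a flat horizontal function, built from the term's coefficient subvector
#' and its covariance at effective rank close to the term's edf (the
#' standard penalized-smooth Wald-like test). Terms penalized to zero edf
#' carry no information and are reported with p = 1 and flagged.
#'
#' @param fit An [fit_gamm()] result.
#' @param term Optional canonical term name(s) to return (e.g. `"order"`);
#'   default all.
#' @return Data.frame with `term`, `label`, `edf`, `ref_df`, `statistic`,
#'   `p_value`, `flag_zero_edf`.
#' @export
test_smooth <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "egg_gamm"))
  lab <- term_labels(fit$design, fit$frame)
  st <- fit$s_table
  i <- match(lab, rownames(st))
  out <- data.frame(term = names(lab), label = unname(lab),
                    edf = st[i, "edf"], ref_df = st[i, "Ref.df"],
                    statistic = st[i, "F"],
                    p_value = st[i, "p-value"], row.names = NULL)
  out$flag_zero_edf <- out$edf < 0.01
  out$p_value[out$flag_zero_edf] <- 1
  if (!is.null(term)) {
    if (!all(term %in% out$term))
      stop("term not in fit: ", paste(setdiff(term, out$term), collapse = ", "))
    out <- out[out$term %in% term, ]
  }
  out
}

#' Partition explained deviance across model terms
#'
#' `drop_one` refits the model without each term and reports the loss in
#' explained deviance (percentage points of null deviance); `add_one` fits
#' each term alone (plus intercept) and reports its solitary explained
#' deviance. Both are computed under the same fixed AR(1) parameter, the
#' one estimated for the full model, so partial models share the full
#' model's residual covariance.
#'
#' @param design A [model_design()].
#' @param frame A [build_model_frame()] result.
#' @param rho Fixed AR(1) parameter (default 0), typically the two-pass
#'   estimate.
#' @param method `"drop_one"`, `"add_one"`, or `"both"`.
#' @param groups Optional named list of term vectors partitioned as a
#'   unit, e.g. `list(order_all = c("order", "order_x_clutch_size"))` to
#'   account for every term involving laying position together (a main
#'   effect and an interaction surface can trade explained deviance
#'   between them, so grouped shares are the interpretable quantity for
#'   related terms). By default every term forms its own group.
#' @return Data.frame of class `"deviance_partition"` with `term`,
#'   `method`, `share_pct`; attributes `full_dev_expl_pct` and `rho`.
#' @export
deviance_partition <- function(design, frame, rho = 0,
                               method = c("drop_one", "add_one", "both"),
                               groups = NULL) {
  method <- match.arg(method)
  methods <- if (method == "both") c("drop_one", "add_one") else method
  full <- fit_gamm(design, frame, rho = rho)
  terms <- names(design_terms(design, frame))
  if (is.null(groups)) groups <- setNames(as.list(terms), terms)
  bad <- setdiff(unlist(groups), terms)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (m in methods) {
    for (g in names(groups)) {
      t <- groups[[g]]
      share <- if (m == "drop_one") {
        if (length(setdiff(terms, t)) == 0) {
          100 * full$dev_expl
        } else {
          part <- refit_design(design, frame, rho, drop = t)
          100 * (full$dev_expl - part$dev_expl)
        }
      } else {
        part <- refit_design(design, frame, rho, only = t)
        100 * part$dev_expl
      }
      rows[[length(rows) + 1]] <-
        data.frame(term = g, method = m, share_pct = share)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "full_dev_expl_pct") <- 100 * full$dev_expl
  attr(out, "rho") <- rho
  class(out) <- c("deviance_partition", "data.frame")
  out
}

# refit with terms dropped or restricted, same rho and data ordering
refit_design <- function(design, frame, rho, drop = NULL, only = NULL) {
  frame <- frame[order(frame$year, as.character(frame$clutch_id),
                       frame$position), ]
  ar_start <- !duplicated(frame$clutch_id)
  form <- design_formula(design, frame, drop = drop, only = only)
  environment(form) <- environment()
  fit <- fit_penalized(form, frame, rho, ar_start, design$response)
  list(fit = fit, dev_expl = as.numeric(summary(fit)$dev.expl))
}

#' Concurvity report
#'
#' Observed concurvity of each term: the proportion of the term's fitted
#' contribution lying in the span of all other terms' bases, together with
#' the basis-level worst case; values are clipped to [0, 1]. The pairwise
#' observed matrix is included so specific term pairs (e.g. clutch
#' intercepts against a covariate that varies mostly between clutches) can
#' be inspected.
#'
#' @param fit An [fit_gamm()] result with at least two terms.
#' @return List of class `"concurvity_report"`: `summary` (term, worst,
#'   observed, flag_zero_contribution) and `pairwise_observed` matrix.
#' @export
concurvity_report <- function(fit) {
  stopifnot(inherits(fit, "egg_gamm"))
  if (length(fit$gam$smooth) < 2) stop("need at least two terms")
  con <- mgcv::concurvity(fit$gam, full = TRUE)
  pair <- mgcv::concurvity(fit$gam, full = FALSE)$observed
  clip01 <- function(m) {
    m[!is.finite(m)] <- 0
    pmin(pmax(m, 0), 1)
  }
  lab <- term_labels(fit$design, fit$frame)
  i <- match(lab, colnames(con))
  zero <- !is.finite(con["observed", i]) | is.nan(con["observed", i])
  out <- list(
    summary = data.frame(term = names(lab), label = unname(lab),
                         worst = clip01(con["worst", i]),
                         observed = clip01(con["observed", i]),
                         flag_zero_contribution = zero, row.names = NULL),
    pairwise_observed = clip01(pair))
  class(out) <- "concurvity_report"
  out
}

#' @export
print.concurvity_report <- function(x, ...) {
  cat("Concurvity (observed / worst-case), clipped to [0, 1]\n")
  print(transform(x$summary, worst = round(worst, 3),
                  observed = round(observed, 3)))
  invisible(x)
}

#' Basis-dimension sufficiency check
#'
#' Per smooth term, reports the basis dimension k', the effective degrees
#' of freedom after penalization, and the residual-pattern k-index (ratio
#' of the variance of nearest-neighbour residual differences, ordered by
#' the term's covariate, to the overall residual variance; values
#' substantially below 1 flag possible under-smoothing). Terms whose edf
#' is within 0.1 of k' are flagged to raise k. The k-index p-value comes
#' from a randomization test and therefore uses the RNG.
#'
#' @param fit An [fit_gamm()] result.
#' @return Data.frame with `term`, `k_prime`, `edf`, `k_index`, `p_value`,
#'   `flag_raise_k`.
#' @export
basis_check <- function(fit) {
  stopifnot(inherits(fit, "egg_gamm"))
  kc <- mgcv::k.check(fit$gam)
  lab <- term_labels(fit$design, fit$frame)
  rn <- sub("[0-9]+$", "", rownames(kc))
  i <- match(lab, rownames(kc))
  i[is.na(i)] <- match(lab[is.na(i)], rn)
  out <- data.frame(term = names(lab),
                    k_prime = kc[i, "k'"], edf = kc[i, "edf"],
                    k_index = kc[i, "k-index"],
                    p_value = kc[i, "p-value"], row.names = NULL)
  out$flag_raise_k <- !is.na(out$k_prime) & (out$k_prime - out$edf) < 0.1
  out
}

#' Partial-effect curve of the laying-order effect
#'
#' Predicted laying-order effect over a grid of within-clutch standard
#' scores, holding the other covariates at their scaled means (0) and the
#' random intercepts at 0 — the prediction "excluding effects of other
#' variables". All smooth terms involving laying position (the main smooth
#' plus any interaction surface evaluated at the other covariate's mean)
#' contribute; the per-clutch factor smooth, if present, does not. The
#' curve is returned both in mm^3 and as percent deviation from the
#' dataset mean volume, linked exactly by that mean.
#'
#' @param fit An [fit_gamm()] result containing the position smooth.
#' @param z Optional grid of standard scores; default 101 points spanning
#'   the observed `position_z` range.
#' @param n_grid Grid size when `z` is NULL.
#' @return Data.frame of class `"order_effect_curve"`: `z`,
#'   `deviation_scaled`, `se_scaled`, `deviation_mm3`, `volume_mm3`,
#'   `deviation_pct`, `extrapolated`; attribute `mean_volume_mm3`.
#' @export
predict_order_effect <- function(fit, z = NULL, n_grid = 101) {
  stopifnot(inherits(fit, "egg_gamm"))
  sm <- fit$gam$smooth
  use <- vapply(sm, function(s)
    "position_z" %in% s$term && !("clutch_id" %in% s$term), logical(1))
  if (!any(use)) stop("fit contains no laying-position term")
  obs <- range(fit$frame$position_z)
  if (is.null(z)) z <- seq(obs[1], obs[2], length.out = n_grid)
  nd <- data.frame(position_z = z, clutch_size_scaled = 0, tmin3_scaled = 0,
                   clutch_id = factor(levels(fit$frame$clutch_id)[1],
                                      levels = levels(fit$frame$clutch_id)),
                   year_f = factor(levels(fit$frame$year_f)[1],
                                   levels = levels(fit$frame$year_f)))
  Xp <- predict(fit$gam, newdata = nd, type = "lpmatrix")
  cols <- unlist(lapply(sm[use], function(s) s$first.para:s$last.para))
  beta <- coef(fit$gam)
  eff <- as.numeric(Xp[, cols, drop = FALSE] %*% beta[cols])
  V <- fit$gam$Vp[cols, cols, drop = FALSE]
  se <- sqrt(pmax(0, rowSums((Xp[, cols, drop = FALSE] %*% V) *
                               Xp[, cols, drop = FALSE])))
  rec <- fit$scaling_record
  ctr <- rec$volume_scaled$center
  scl <- rec$volume_scaled$scale
  out <- data.frame(
    z = z,
    deviation_scaled = eff,
    se_scaled = se,
    deviation_mm3 = eff * scl,
    volume_mm3 = ctr + eff * scl,
    deviation_pct = 100 * eff * scl / ctr,
    extrapolated = z < obs[1] | z > obs[2])
  attr(out, "mean_volume_mm3") <- ctr
  attr(out, "response_scale") <- scl
  class(out) <- c("order_effect_curve", "data.frame")
  out
}

#' Base-graphics plot of the laying-order effect curve
#'
#' Shows the percent-deviation curve with a pointwise 95% band and the
#' zero line (the dataset mean volume).
#'
#' @param x An [predict_order_effect()] result.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.order_effect_curve <- function(x, ...) {
  rec_mean <- attr(x, "mean_volume_mm3")
  se_pct <- 100 * x$se_scaled * attr(x, "response_scale") / rec_mean
  plot(x$z, x$deviation_pct, type = "l", lwd = 2,
       ylim = range(c(x$deviation_pct - 1.96 * se_pct,
                      x$deviation_pct + 1.96 * se_pct)),
       xlab = "laying position (within-clutch standard score)",
       ylab = "deviation from mean egg volume (%)", ...)
  graphics::abline(h = 0, col = "red")
  graphics::lines(x$z, x$deviation_pct + 1.96 * se_pct, lty = 2)
  graphics::lines(x$z, x$deviation_pct - 1.96 * se_pct, lty = 2)
  invisible(x)
}
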