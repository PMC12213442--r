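#' Egg volume from length and breadth
#'
#' Computes egg volume (mm^3) from external length and maximum breadth (mm)
#' using the species-calibrated formula \eqn{v = c_1 L B^2 + c_2}. The
#' default constants were estimated for great tits; both are overridable for
#' other species.
#'
#' @param length_mm Egg length in mm (vectorised). Must be positive.
#' @param breadth_mm Egg breadth in mm (vectorised). Must be positive.
#' @param coef Numeric length-2 vector `c(c1, c2)` of the volume formula.
#' @return Numeric vector of volumes in mm^3.
#' @examples
#' compute_volume(17.8, 13.5)
#' @export
compute_volume <- function(length_mm, breadth_mm, coef = c(0.4673, 0.042)) {
  stopifnot(is.numeric(length_mm), is.numeric(breadth_mm), length(coef) == 2)
  if (any(!is.finite(length_mm)) || any(!is.finite(breadth_mm)))
    stop("non-finite egg measurement")
  if (any(length_mm <= 0) || any(breadth_mm <= 0))
    stop("invalid measurement: length and breadth must be positive")
  coef[1] * length_mm * breadth_mm^2 + coef[2]
}

#' Egg sphericity (breadth/length)
#'
#' Sphericity is the ratio breadth/length; it equals 1 for a sphere-like
#' profile and lies in (0, 1] whenever length >= breadth.
#'
#' @inheritParams compute_volume
#' @return Numeric vector of dimensionless ratios.
#' @export
compute_sphericity <- function(length_mm, breadth_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0))
    stop("invalid measurement: length must be positive")
  if (any(!is.finite(breadth_mm)) || any(breadth_mm <= 0))
    stop("invalid measurement: breadth must be positive")
  breadth_mm / length_mm
}

#' Invert the volume formula at a given sphericity
#'
#' Given a target volume and sphericity s = B/L, solves
#' \eqn{v = c_1 L (sL)^2 + c_2} for length and breadth. This is the exact
#' inverse of [compute_volume()] and is used by the synthetic-data generator
#' so that geometry derivations are exercised end to end.
#'
#' @param volume_mm3 Target volume in mm^3 (vectorised).
#' @param sphericity Breadth/length ratio in (0, 1].
#' @param coef Volume-formula constants as in [compute_volume()].
#' @return A data.frame with columns `length_mm` and `breadth_mm`.
#' @export
back_solve_geometry <- function(volume_mm3, sphericity, coef = c(0.4673, 0.042)) {
  if (any(!is.finite(volume_mm3)) || any(volume_mm3 <= coef[2]))
    stop("invalid config: volume must exceed the formula constant ", coef[2],
         " mm^3 for the geometry back-solve")
  if (any(sphericity <= 0) || any(sphericity > 1))
    stop("sphericity must lie in (0, 1]")
  len <- ((volume_mm3 - coef[2]) / (coef[1] * sphericity^2))^(1 / 3)
  data.frame(length_mm = len, breadth_mm = sphericity * len)
}

#' Last-egg deviation statistic D
#'
#' The classical single-number summary of within-clutch investment: the
#' deviation of the final egg's volume from the clutch mean volume,
#' expressed as a percentage of that mean. By default the mean is taken
#' over all eggs including the last; `exclude_last = TRUE` reproduces the
#' alternative literature convention in which the last egg is excluded from
#' the reference mean.
#'
#' @param volumes Numeric vector of egg volumes ordered by laying position.
#' @param exclude_last Logical; exclude the final egg from the reference
#'   mean?
#' @return D as a percentage of the reference mean.
#' @examples
#' last_egg_deviation(c(1400, 1500, 1600))
#' @export
last_egg_deviation <- function(volumes, exclude_last = FALSE) {
  if (length(volumes) < 2)
    stop("D requires at least 2 eggs")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("volumes must be positive and finite")
  ref <- if (exclude_last) mean(volumes[-length(volumes)]) else mean(volumes)
  100 * (volumes[length(volumes)] - ref) / ref
}

#' Classify clutches as first or late within each year
#'
#' Within each year the earliest first-egg date defines day 0; clutches
#' whose first egg falls within the following `window_days` days
#' (inclusive boundary) are classified `"first"`, the rest `"late"`.
#'
#' @param first_egg_date Date (or coercible) vector, one per clutch.
#' @param year Vector of calendar years, one per clutch.
#' @param window_days Inclusive window length in days (default 30).
#' @return Factor with levels `"first"` and `"late"`, one per clutch.
#' @export
classify_clutch_lateness <- function(first_egg_date, year, window_days = 30) {
  first_egg_date <- as.Date(first_egg_date)
  if (any(is.na(first_egg_date))) stop("missing first-egg dates")
  if (length(first_egg_date) != length(year))
    stop("first_egg_date and year lengths differ")
  out <- character(length(year))
  for (y in unique(year)) {
    i <- which(year == y)
    day0 <- min(first_egg_date[i])
    offset <- as.numeric(first_egg_date[i] - day0)
    out[i] <- ifelse(offset <= window_days, "first", "late")
  }
  factor(out, levels = c("first", "late"))
}

#' Append derived geometry columns to an egg table
#'
#' Adds `volume_mm3` and `sphericity` columns computed from `length_mm` and
#' `breadth_mm`. Input columns are never overwritten.
#'
#' @param eggs Egg table with columns `length_mm` and `breadth_mm`.
#' @param coef Volume-formula constants, see [compute_volume()].
#' @return The egg table with `volume_mm3` and `sphericity` appended.
#' @export
add_egg_geometry <- function(eggs, coef = c(0.4673, 0.042)) {
  stopifnot(all(c("length_mm", "breadth_mm") %in% names(eggs)))
  eggs$volume_mm3 <- compute_volume(eggs$length_mm, eggs$breadth_mm, coef)
  eggs$sphericity <- compute_sphericity(eggs$length_mm, eggs$breadth_mm)
  eggs
}

#' Per-clutch summary with D statistic and lateness class
#'
#' @param eggs Egg table with columns `clutch_id`, `year`, `lay_date`,
#'   `position`, and either `volume_mm3` or `length_mm`/`breadth_mm`.
#' @param coef Volume-formula constants used if volumes must be derived.
#' @param exclude_last Convention for [last_egg_deviation()].
#' @param window_days Lateness window, see [classify_clutch_lateness()].
#' @return A data.frame with one row per clutch: `clutch_id`, `year`,
#'   `clutch_size`, `first_egg_date`, `lateness`, `mean_volume_mm3`,
#'   `d_statistic_pct`.
#' @export
clutch_summaries <- function(eggs, coef = c(0.4673, 0.042),
                             exclude_last = FALSE, window_days = 30) {
  if (!"volume_mm3" %in% names(eggs)) eggs <- add_egg_geometry(eggs, coef)
  eggs <- eggs[order(eggs$clutch_id, eggs$position), ]
  ids <- unique(eggs$clutch_id)
  rows <- lapply(ids, function(id) {
    cl <- eggs[eggs$clutch_id == id, ]
    data.frame(
      clutch_id = id,
      year = cl$year[1],
      clutch_size = nrow(cl),
      first_egg_date = min(as.Date(cl$lay_date)),
      mean_volume_mm3 = mean(cl$volume_mm3),
      d_statistic_pct = if (nrow(cl) >= 2)
        last_egg_deviation(cl$volume_mm3, exclude_last) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out$lateness <- classify_clutch_lateness(out$first_egg_date, out$year,
                                           window_days)
  out[, c("clutch_id", "year", "clutch_size", "first_egg_date", "lateness",
          "mean_volume_mm3", "d_statistic_pct")]
}
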