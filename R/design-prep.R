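#' Dataset-wide standard scoring
#'
#' Centres and scales by the sample (n-1 denominator) standard deviation,
#' returning the scaling constants so every scaled column can be inverted
#' exactly.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with `values` (scaled), `center` (mean) and `scale`
#'   (sample sd).
#' @examples
#' zscore_dataset(c(0, 1))
#' @export
zscore_dataset <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values")
  if (length(unique(values)) < 2) stop("constant column: cannot scale")
  m <- mean(values)
  s <- sd(values)
  list(values = (values - m) / s, center = m, scale = s)
}

#' Invert a dataset scaling
#'
#' @param values Scaled values.
#' @param center,scale Constants returned by [zscore_dataset()].
#' @return The unscaled values.
#' @export
unscale <- function(values, center, scale) values * scale + center

#' Within-clutch standard scores of laying position
#'
#' Per clutch, positions are centred on their mean and divided by their
#' sample standard deviation, so that clutches of different sizes share one
#' functional scale for the laying-order effect.
#'
#' @param position Integer laying positions.
#' @param clutch_id Clutch identifier aligned with `position`.
#' @return Numeric vector of within-clutch standard scores.
#' @examples
#' zscore_within_clutch(c(1, 2, 3), c("a", "a", "a"))
#' @export
zscore_within_clutch <- function(position, clutch_id) {
  stopifnot(length(position) == length(clutch_id))
  out <- numeric(length(position))
  for (id in unique(clutch_id)) {
    i <- which(clutch_id == id)
    if (length(i) < 2)
      stop("clutch of size 1 cannot be standard-scored: ", id)
    out[i] <- (position[i] - mean(position[i])) / sd(position[i])
  }
  out
}

#' Mean minimum temperature over the egg-formation window
#'
#' Averages daily minimum temperature over the 3 calendar days strictly
#' preceding each laying date (the laying day itself is excluded), the
#' period of egg formation. Missing days are an error unless single-day
#' linear interpolation is enabled.
#'
#' @param temperature Data.frame with columns `date` (Date or coercible)
#'   and `tmin_c`.
#' @param lay_date Laying date(s).
#' @param window_days Number of preceding days to average (default 3).
#' @param interpolate Logical; fill isolated missing days by linear
#'   interpolation over calendar time?
#' @return Numeric vector of window means, degrees C.
#' @export
mean_tmin_window <- function(temperature, lay_date, window_days = 3,
                             interpolate = FALSE) {
  stopifnot(all(c("date", "tmin_c") %in% names(temperature)))
  dates <- as.Date(temperature$date)
  lay_date <- as.Date(lay_date)
  lookup <- setNames(temperature$tmin_c, as.character(dates))
  vapply(seq_along(lay_date), function(i) {
    need <- lay_date[i] - seq_len(window_days)
    v <- lookup[as.character(need)]
    if (any(is.na(v))) {
      if (!interpolate)
        stop("temperature table missing day(s) ",
             paste(need[is.na(v)], collapse = ", "),
             " in the formation window of ", lay_date[i])
      fit <- approx(as.numeric(dates), temperature$tmin_c,
                    xout = as.numeric(need[is.na(v)]), rule = 1)
      if (any(is.na(fit$y)))
        stop("cannot interpolate temperature outside the observed range")
      v[is.na(v)] <- fit$y
    }
    mean(v)
  }, numeric(1))
}

#' Pairwise Pearson collinearity screen
#'
#' Computes the full symmetric Pearson correlation matrix among candidate
#' covariates and flags pairs whose |r| exceeds a threshold for exclusion
#' (the screen that removes laying date when it tracks the seasonal
#' temperature trend).
#'
#' @param covariates Data.frame of numeric candidate covariates
#'   (>= 3 rows).
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.7).
#' @return List with `correlations` (matrix), `flagged` (data.frame of
#'   var1, var2, r) and `threshold`.
#' @export
collinearity_screen <- function(covariates, threshold = 0.7) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) < 3) stop("need at least 3 rows")
  num <- vapply(covariates, is.numeric, logical(1))
  covariates <- covariates[num]
  csd <- vapply(covariates, sd, numeric(1))
  if (any(csd == 0))
    stop("constant column(s): ", paste(names(covariates)[csd == 0],
                                       collapse = ", "))
  r <- cor(covariates)
  flagged <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  flags <- data.frame(var1 = rownames(r)[flagged[, 1]],
                      var2 = colnames(r)[flagged[, 2]],
                      r = r[flagged])
  list(correlations = r, flagged = flags, threshold = threshold)
}

#' Build the scaled model frame
#'
#' Derives volume and sphericity if absent, computes the 3-day formation
#' window temperature for each egg, and assembles the scaled columns used
#' by the model: the response scaled over the whole dataset, laying
#' position standard-scored within each clutch, and clutch size and window
#' temperature scaled over the whole dataset. The scaling constants for
#' every scaled column are stored in the `"scaling_record"` attribute
#' (retrievable with [scaling_record()]) and suffice to invert each scaling
#' exactly. Laying date (day of year) is carried along for the
#' collinearity screen but is not part of the default design.
#'
#' @param eggs Egg table: `clutch_id`, `year`, `lay_date`, `position`,
#'   `length_mm`, `breadth_mm` (or a precomputed `volume_mm3`).
#' @param temperature Temperature table: `date`, `tmin_c`.
#' @param response Which derived response to scale: `"volume"` (default),
#'   `"length"`, `"breadth"` or `"sphericity"`.
#' @param volume_coef Volume-formula constants, see [compute_volume()].
#' @param interpolate_temps Passed to [mean_tmin_window()].
#' @return A data.frame of class `"model_frame"`, ordered by year, clutch
#'   and position, with columns `clutch_id` and `year_f` (factors), `year`,
#'   `position`, `lay_date`, `lay_doy`, `clutch_size`, `volume_mm3`,
#'   `sphericity`, `tmin3_c`, `volume_scaled`, `position_z`,
#'   `clutch_size_scaled`, `tmin3_scaled`.
#' @export
build_model_frame <- function(eggs, temperature, response = "volume",
                              volume_coef = c(0.4673, 0.042),
                              interpolate_temps = FALSE) {
  eggs <- as.data.frame(eggs)
  eggs$lay_date <- as.Date(eggs$lay_date)
  if (!all(c("volume_mm3", "sphericity") %in% names(eggs)))
    eggs <- add_egg_geometry(eggs, volume_coef)
  eggs <- eggs[order(eggs$year, eggs$clutch_id, eggs$position), ]
  sizes <- table(eggs$clutch_id)
  eggs$clutch_size <- as.integer(sizes[as.character(eggs$clutch_id)])
  eggs$tmin3_c <- mean_tmin_window(temperature, eggs$lay_date,
                                   interpolate = interpolate_temps)
  eggs$lay_doy <- as.integer(format(eggs$lay_date, "%j"))

  resp_col <- switch(response,
    volume = "volume_mm3", length = "length_mm", breadth = "breadth_mm",
    sphericity = "sphericity",
    stop("unknown response: ", response))
  sc_y <- zscore_dataset(eggs[[resp_col]])
  sc_cs <- zscore_dataset(eggs$clutch_size)
  sc_t <- zscore_dataset(eggs$tmin3_c)

  frame <- data.frame(
    clutch_id = factor(eggs$clutch_id),
    year = eggs$year,
    year_f = factor(eggs$year),
    position = eggs$position,
    lay_date = eggs$lay_date,
    lay_doy = eggs$lay_doy,
    clutch_size = eggs$clutch_size,
    volume_mm3 = eggs$volume_mm3,
    length_mm = eggs$length_mm,
    breadth_mm = eggs$breadth_mm,
    sphericity = eggs$sphericity,
    tmin3_c = eggs$tmin3_c,
    volume_scaled = sc_y$values,
    position_z = zscore_within_clutch(eggs$position, as.character(eggs$clutch_id)),
    clutch_size_scaled = sc_cs$values,
    tmin3_scaled = sc_t$values)
  rownames(frame) <- NULL

  attr(frame, "scaling_record") <- list(
    response = response,
    response_column = resp_col,
    volume_scaled = list(center = sc_y$center, scale = sc_y$scale),
    clutch_size_scaled = list(center = sc_cs$center, scale = sc_cs$scale),
    tmin3_scaled = list(center = sc_t$center, scale = sc_t$scale),
    mean_volume_mm3 = mean(eggs$volume_mm3))
  class(frame) <- c("model_frame", "data.frame")
  frame
}

#' Retrieve the scaling record of a model frame
#'
#' @param frame A [build_model_frame()] result.
#' @return The list of scaling constants stored with the frame.
#' @export
scaling_record <- function(frame) {
  rec <- attr(frame, "scaling_record")
  if (is.null(rec)) stop("no scaling record: not a model frame?")
  rec
}
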