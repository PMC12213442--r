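#' Validate egg and temperature tables
#'
#' Enforces the data semantics the model assumes: required columns;
#' positive measurements with length >= breadth; positions exactly
#' 1..clutch_size with no gaps or duplicates; consecutive positions laid on
#' consecutive calendar days (one egg per day; relax with
#' `strict_dates = FALSE`); one year per clutch; and, when a temperature
#' table is supplied, coverage of every egg's 3-day formation window.
#'
#' @param eggs Egg table (`clutch_id`, `year`, `lay_date`, `position`,
#'   `length_mm`, `breadth_mm`).
#' @param temperature Optional temperature table (`date`, `tmin_c`).
#' @param strict_dates Require one egg per calendar day?
#' @param interpolate_temps Allow interpolation for missing window days
#'   (downgrades missing-day errors to warnings)?
#' @return List with `ok` (no hard errors) and `issues` (data.frame:
#'   `severity`, `clutch_id`, `message`).
#' @export
validate_inputs <- function(eggs, temperature = NULL, strict_dates = TRUE,
                            interpolate_temps = FALSE) {
  issues <- list()
  note <- function(severity, clutch_id, message)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, clutch_id = as.character(clutch_id),
      message = message)

  required <- c("clutch_id", "year", "lay_date", "position",
                "length_mm", "breadth_mm")
  missing_cols <- setdiff(required, names(eggs))
  if (length(missing_cols)) {
    note("error", NA, paste("missing egg columns:",
                            paste(missing_cols, collapse = ", ")))
  } else {
    eggs$lay_date <- as.Date(eggs$lay_date)
    bad <- which(!is.finite(eggs$length_mm) | !is.finite(eggs$breadth_mm) |
                   eggs$length_mm <= 0 | eggs$breadth_mm <= 0)
    for (i in bad)
      note("error", eggs$clutch_id[i],
           sprintf("row %d: non-positive length/breadth", i))
    bad <- which(eggs$length_mm < eggs$breadth_mm)
    for (i in bad)
      note("error", eggs$clutch_id[i],
           sprintf("row %d: breadth exceeds length", i))
    if (any(is.na(eggs$lay_date)))
      note("error", NA, "unparseable lay_date value(s)")

    for (id in unique(eggs$clutch_id)) {
      cl <- eggs[eggs$clutch_id == id, ]
      cl <- cl[order(cl$position), ]
      if (!identical(as.integer(cl$position), seq_len(nrow(cl))))
        note("error", id,
             "positions are not exactly 1..clutch_size (gap or duplicate)")
      if (length(unique(cl$year)) > 1)
        note("error", id, "clutch spans multiple years")
      if (nrow(cl) >= 2 && !any(is.na(cl$lay_date))) {
        gaps <- diff(as.numeric(cl$lay_date))
        if (any(gaps != 1))
          note(if (strict_dates) "error" else "warning", id,
               "consecutive positions are not one day apart")
      }
    }

    if (!is.null(temperature)) {
      if (!all(c("date", "tmin_c") %in% names(temperature))) {
        note("error", NA, "temperature table lacks date/tmin_c columns")
      } else if (!any(is.na(eggs$lay_date))) {
        have <- as.character(as.Date(temperature$date))
        need_all <- unique(unlist(lapply(eggs$lay_date, function(d)
          as.character(d - 1:3))))
        miss <- setdiff(need_all, have)
        if (length(miss))
          note(if (interpolate_temps) "warning" else "error", NA,
               paste("temperature table missing formation-window day(s):",
                     paste(sort(miss), collapse = ", ")))
      }
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), clutch_id = character(),
               message = character())
  list(ok = !any(issues$severity == "error"), issues = issues)
}

#' Load an egg table from CSV with optional column mapping
#'
#' `column_map` is a named character vector mapping the standard names
#' (`clutch_id`, `year`, `lay_date`, `position`, `length_mm`,
#' `breadth_mm`) to the columns of the file, so external deposits with
#' their own naming can be ingested without editing the file.
#'
#' @param path CSV path.
#' @param column_map Named character vector standard -> file column, or
#'   NULL if the file already uses standard names.
#' @return Egg table data.frame.
#' @export
load_egg_table <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- apply_column_map(df, column_map)
  df$lay_date <- as.Date(df$lay_date)
  df
}

#' Load a temperature table from CSV with optional column mapping
#'
#' @param path CSV path.
#' @param column_map Named character vector mapping `date` and `tmin_c` to
#'   the file's columns, or NULL.
#' @return Temperature table data.frame.
#' @export
load_temperature_table <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- apply_column_map(df, column_map)
  df$date <- as.Date(df$date)
  df
}

apply_column_map <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  missing_src <- setdiff(unname(column_map), names(df))
  if (length(missing_src))
    stop("column_map refers to absent column(s): ",
         paste(missing_src, collapse = ", "))
  for (std in names(column_map)) names(df)[names(df) == column_map[[std]]] <- std
  df
}

#' Full-analysis run configuration
#'
#' Bundles the input mode (simulate from a [synthetic_config()], or load
#' CSV files), the [model_design()], and the analysis toggles. Exactly one
#' input mode is active. The seed governs every source of randomness in a
#' run and is recorded in the run metadata.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param synthetic A [synthetic_config()] (simulate mode).
#' @param eggs_file,temperature_file CSV paths (files mode).
#' @param egg_column_map,temperature_column_map Column maps for the
#'   loaders.
#' @param design A [model_design()].
#' @param partition_method Method for [deviance_partition()].
#' @param d_exclude_last D-statistic convention, see
#'   [last_egg_deviation()].
#' @param lateness_window_days See [classify_clutch_lateness()].
#' @param interpolate_temps Allow temperature interpolation?
#' @param max_lag Maximum lag of the residual-dependence analysis
#'   (default: max clutch size - 2).
#' @param seed Integer seed for the run.
#' @param verbose Narrate pipeline stages?
#' @return List of class `"run_config"`.
#' @export
run_config <- function(mode = c("simulate", "files"),
                       synthetic = synthetic_config(),
                       eggs_file = NULL, temperature_file = NULL,
                       egg_column_map = NULL, temperature_column_map = NULL,
                       design = model_design(),
                       partition_method = "drop_one",
                       d_exclude_last = FALSE,
                       lateness_window_days = 30,
                       interpolate_temps = FALSE,
                       max_lag = NULL,
                       seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "files" && (is.null(eggs_file) || is.null(temperature_file)))
    stop("files mode requires eggs_file and temperature_file")
  structure(list(mode = mode, synthetic = synthetic,
                 eggs_file = eggs_file, temperature_file = temperature_file,
                 egg_column_map = egg_column_map,
                 temperature_column_map = temperature_column_map,
                 design = design, partition_method = partition_method,
                 d_exclude_last = d_exclude_last,
                 lateness_window_days = lateness_window_days,
                 interpolate_temps = interpolate_temps, max_lag = max_lag,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

#' Run the full within-clutch investment analysis
#'
#' Executes the whole pipeline: simulate or load the data, validate,
#' derive geometry and clutch summaries (including the D statistic), build
#' the scaled model frame, run the two-pass AR(1) GAMM, compute
#' diagnostics (smooth tests, deviance partition at the pass-1 rho,
#' concurvity, basis checks), analyse per-clutch residual dependence for
#' raw and AR-standardized pass-2 residuals, and predict the
#' laying-order partial-effect curve. When `out_dir` is given, writes
#' `terms.csv`, `partition.csv`, `concurvity.csv`, `lags.csv`,
#' `lag_summary.csv`, `clutches.csv`, `order_effect_curve.csv`,
#' `eggs.csv`/`temperature.csv` (simulate mode) and `run.json`. Outputs
#' carry no timestamps, so a given config and seed reproduce byte-identical
#' artifacts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or NULL to skip writing.
#' @return Invisibly, a list of class `"clutchcurve_run"` with all
#'   intermediate objects (`data`, `clutches`, `frame`, `two_pass`,
#'   `terms`, `partition`, `concurvity`, `basis`, `lags`, `lag_summary`,
#'   `curve`, `meta`).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(...)
  set.seed(config$seed)

  if (config$mode == "simulate") {
    cfg <- config$synthetic
    cfg$seed <- config$seed
    sim <- generate_dataset(structure(cfg, class = "synthetic_config"))
    eggs <- sim$eggs
    temperature <- sim$temperature
  } else {
    sim <- NULL
    eggs <- load_egg_table(config$eggs_file, config$egg_column_map)
    temperature <- load_temperature_table(config$temperature_file,
                                          config$temperature_column_map)
  }
  say(sprintf("stage data: %d eggs, %d clutches", nrow(eggs),
              length(unique(eggs$clutch_id))))

  val <- validate_inputs(eggs, temperature,
                         interpolate_temps = config$interpolate_temps)
  if (!val$ok) {
    bad <- val$issues[val$issues$severity == "error", ]
    stop("stage validate failed:\n",
         paste(sprintf("  [%s] %s", bad$clutch_id, bad$message),
               collapse = "\n"))
  }

  eggs <- add_egg_geometry(eggs)
  clutches <- clutch_summaries(eggs, exclude_last = config$d_exclude_last,
                               window_days = config$lateness_window_days)
  say(sprintf("stage geometry: mean volume %.2f mm^3",
              mean(eggs$volume_mm3)))

  frame <- build_model_frame(eggs, temperature,
                             interpolate_temps = config$interpolate_temps)
  tp <- two_pass_ar_fit(config$design, frame)
  say(sprintf("stage fit: pass-1 rho %.3f, pass-2 deviance explained %.1f%%",
              tp$rho$rho, 100 * tp$pass2$dev_expl))

  terms <- test_smooth(tp$pass2)
  part <- deviance_partition(config$design, frame, rho = tp$rho$rho,
                             method = config$partition_method)
  conc <- concurvity_report(tp$pass2)
  basis <- basis_check(tp$pass2)

  band <- whitenoise_band(mean(clutches$clutch_size))
  lags <- rbind(
    residual_lag_coefs(tp$pass2$residuals_raw, tp$pass2$frame$clutch_id,
                       tp$pass2$frame$position, residual_type = "raw",
                       max_lag = config$max_lag),
    residual_lag_coefs(tp$pass2$residuals_std, tp$pass2$frame$clutch_id,
                       tp$pass2$frame$position,
                       residual_type = "standardized",
                       max_lag = config$max_lag))
  lag_summary <- aggregate_lag_stats(lags, band)
  say(sprintf("stage autocorr: band +/-%.3f, %d lag rows", band, nrow(lags)))

  curve <- predict_order_effect(tp$pass2)

  meta <- list(
    seed = config$seed, mode = config$mode,
    n_eggs = nrow(eggs), n_clutches = nrow(clutches),
    mean_volume_mm3 = mean(eggs$volume_mm3),
    clutch_mean_cv_pct = 100 * sd(clutches$mean_volume_mm3) /
      mean(clutches$mean_volume_mm3),
    mean_clutch_size = mean(clutches$clutch_size),
    whitenoise_band_halfwidth = band,
    pass1_rho = tp$rho$rho, pass1_t = tp$rho$t, pass1_df = tp$rho$df,
    pass1_p = tp$rho$p_value,
    pass2_rho_used = tp$pass2$rho,
    dev_expl_pct = 100 * tp$pass2$dev_expl,
    full_dev_expl_pct = attr(part, "full_dev_expl_pct"),
    d_convention_exclude_last = config$d_exclude_last,
    design_terms = names(design_terms(config$design)))

  out <- structure(list(
    data = list(eggs = eggs, temperature = temperature, sim = sim),
    clutches = clutches, frame = frame, two_pass = tp, terms = terms,
    partition = part, concurvity = conc, basis = basis, lags = lags,
    lag_summary = lag_summary, curve = curve, meta = meta,
    config = config), class = "clutchcurve_run")

  if (!is.null(out_dir)) write_run_artifacts(out, out_dir, say)
  invisible(out)
}

write_run_artifacts <- function(run, out_dir, say = function(...) NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    df <- as.data.frame(df)
    for (cn in names(df)) if (inherits(df[[cn]], "Date"))
      df[[cn]] <- format(df[[cn]], "%Y-%m-%d")
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(run$terms, "terms.csv")
  wcsv(run$partition, "partition.csv")
  wcsv(run$concurvity$summary, "concurvity.csv")
  wcsv(run$basis, "basis_check.csv")
  wcsv(run$lags, "lags.csv")
  wcsv(run$lag_summary, "lag_summary.csv")
  wcsv(run$clutches, "clutches.csv")
  wcsv(as.data.frame(run$curve), "order_effect_curve.csv")
  if (!is.null(run$data$sim)) {
    wcsv(run$data$sim$eggs, "eggs.csv")
    wcsv(run$data$sim$temperature, "temperature.csv")
  }
  jsonlite::write_json(run$meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("stage report: artifacts written to ", out_dir)
  invisible(out_dir)
}

#' @export
print.clutchcurve_run <- function(x, ...) {
  cat("clutchcurve full-analysis run\n")
  cat(sprintf("  %d eggs / %d clutches; mean volume %.2f mm^3 (clutch-mean CV %.2f%%)\n",
              x$meta$n_eggs, x$meta$n_clutches, x$meta$mean_volume_mm3,
              x$meta$clutch_mean_cv_pct))
  cat(sprintf("  pass-1 rho %.3f (t = %.2f, df = %d); deviance explained %.1f%%\n",
              x$meta$pass1_rho, x$meta$pass1_t, x$meta$pass1_df,
              x$meta$dev_expl_pct))
  cat(sprintf("  order-effect curve: %.2f%% to %.2f%% of mean volume\n",
              min(x$curve$deviation_pct), max(x$curve$deviation_pct)))
  invisible(x)
}

#' Read a run configuration from JSON
#'
#' Reconstructs a [run_config()] (including nested [synthetic_config()]
#' and [model_design()]) from a JSON file holding overrides of the
#' defaults.
#'
#' @param path JSON file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn_args <- js$synthetic
  if (!is.null(syn_args$order_effect_points))
    syn_args$order_effect_points <- as.matrix(syn_args$order_effect_points)
  if (!is.null(syn_args$clutch_size_probs))
    syn_args$clutch_size_probs <- unlist(syn_args$clutch_size_probs)
  syn <- do.call(synthetic_config, syn_args %||% list())
  des <- do.call(model_design, js$design %||% list())
  top <- js[setdiff(names(js), c("synthetic", "design"))]
  top$egg_column_map <- unlist(top$egg_column_map)
  top$temperature_column_map <- unlist(top$temperature_column_map)
  do.call(run_config, c(top, list(synthetic = syn, design = des)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
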