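# End-to-end study orchestration: read weather, compute reference and
# mass-transfer ET0, calibrate on the training representation, validate on
# held-out years, aggregate monthly/seasonal means and render report files.

#' Load daily weather from a delimited text file
#'
#' Comma-delimited with header columns
#' `date, tmax, tmin, tmean, rhmax, rhmin, rhmean, rs, u2`; dates in ISO
#' 8601. Rows violating the physical invariants are dropped with a warning
#' giving the count (see [as_weather()]).
#'
#' @param path Path to the CSV file.
#' @return An `et0_weather` data frame.
#' @export
load_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("weather file is empty: ", path, call. = FALSE)
  as_weather(df)
}

#' Write daily weather to the delimited text format read by [load_weather()]
#'
#' @param records Daily weather data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Average multiple years of daily weather into one season
#'
#' Per-calendar-day (month-day) mean of every weather field across years —
#' the "multi-year average series" representation on which calibration is
#' performed when emulating a long-term study. Output dates are placed in a
#' nominal year (2000) purely to keep the series dated and ordered.
#'
#' @param records Daily weather spanning one or more years.
#' @return An `et0_weather` data frame with one row per calendar day present
#'   in the input.
#' @export
multi_year_average <- function(records) {
  records <- as_weather(records)
  key <- format(records$date, "%m-%d")
  num_cols <- setdiff(weather_columns(), "date")
  agg <- stats::aggregate(records[num_cols], by = list(monthday = key), mean)
  agg$date <- as.Date(paste0("2000-", agg$monthday))
  agg <- agg[order(agg$date), c("date", num_cols)]
  as_weather(agg)
}

#' Study configuration
#'
#' Defaults reproduce the published study design at the Van Edremit station:
#' calibration on the multi-year-average April-October series of the
#' training years, validation per held-out year, soil heat flux 0.
#'
#' @param station [station_meta()].
#' @param train_years,test_years Disjoint integer year vectors.
#' @param season_months Months making up the growing season (default 4:10).
#' @param models Mass-transfer models to include.
#' @param g Soil heat flux, MJ m-2 day-1.
#' @param calibrate_on_average Calibrate on the multi-year average of the
#'   training years (`TRUE`, the published procedure) or on the pooled daily
#'   series (`FALSE`).
#' @param seed Integer seed for any simulation steps.
#' @return A `run_config` list.
#' @export
run_config <- function(station = van_station(),
                       train_years = 2012:2020,
                       test_years = c(2021, 2022),
                       season_months = 4:10,
                       models = mass_transfer_models(),
                       g = 0,
                       calibrate_on_average = TRUE,
                       seed = 1L) {
  if (length(intersect(train_years, test_years))) {
    stop("training and validation years must be disjoint", call. = FALSE)
  }
  if (!all(season_months %in% 1:12)) stop("invalid season months", call. = FALSE)
  bad <- setdiff(models, mass_transfer_models())
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(station = station, train_years = train_years,
                 test_years = test_years, season_months = season_months,
                 models = models, g = g,
                 calibrate_on_average = calibrate_on_average, seed = seed),
            class = "run_config")
}

# monthly equal-weight means of an et0_series; rows ordered by month
monthly_means <- function(series, season_months) {
  mo <- as.integer(format(series$date, "%m"))
  out <- vapply(season_months, function(m) {
    if (!any(mo == m)) return(NA_real_)
    mean(series$et0[mo == m])
  }, numeric(1))
  names(out) <- month.abb[season_months]
  out
}

# one period's worth of series + tables for all models
study_period <- function(weather, config, coefficients = NULL) {
  st <- config$station
  reference <- compute_et0(weather, "fao56pm", station = st, g = config$g)
  originals <- lapply(config$models, function(m) compute_et0(weather, m, station = st))
  names(originals) <- config$models
  out <- list(reference = reference, originals = originals)
  if (!is.null(coefficients)) {
    out$modified <- lapply(config$models, function(m) {
      cf <- coefficients[coefficients$model_id == m, ]
      apply_linear_calibration(originals[[m]], cf$a, cf$b)
    })
    names(out$modified) <- config$models
  }
  out
}

# monthly-mean table in the published layout: months x (reference + models),
# with equal-weight and day-weighted seasonal average rows
monthly_table <- function(period, variant, season_months) {
  cols <- c(list(fao56pm = period$reference),
            if (variant == "original") period$originals else period$modified)
  tab <- vapply(cols, monthly_means, numeric(length(season_months)),
                season_months = season_months)
  avg_equal <- colMeans(tab, na.rm = TRUE)
  avg_daily <- vapply(cols, function(s) mean(s$et0), numeric(1))
  rbind(as.data.frame(tab),
        `Avg.` = avg_equal, `Avg. (day-weighted)` = avg_daily)
}

#' Run the full calibrate/validate study
#'
#' Computes the FAO-56 PM reference and the original mass-transfer series
#' for the training representation (multi-year average by default), fits the
#' linear calibration of each model, produces the modified series, then
#' evaluates original and modified estimates against the reference for the
#' training period and each validation year. Monthly means are equal-weight
#' means of daily values; the seasonal average is the equal-weight mean of
#' the monthly means (a day-weighted alternative row is also reported).
#' Validation-average metrics are arithmetic means of the per-year metrics.
#'
#' @param config A [run_config()].
#' @param weather Daily weather covering the configured years.
#' @return An `et0_report` list: `calibration`, `metrics` (long data frame),
#'   `monthly` (named list of tables), and the underlying `series` so every
#'   reported number can be recomputed from the report itself.
#' @export
run_study <- function(config, weather) {
  stopifnot(inherits(config, "run_config"))
  weather <- as_weather(weather)
  mo <- as.integer(format(weather$date, "%m"))
  weather <- weather[mo %in% config$season_months, , drop = FALSE]
  yr <- as.integer(format(weather$date, "%Y"))

  train_w <- weather[yr %in% config$train_years, , drop = FALSE]
  if (nrow(train_w) == 0) stop("no training data in configured years", call. = FALSE)
  train_rep <- if (config$calibrate_on_average) multi_year_average(train_w) else train_w

  train <- study_period(train_rep, config)
  calibration <- calibrate_all_models(train$reference, train$originals)
  calibration <- calibration[calibration$model_id %in% config$models, ]
  train <- study_period(train_rep, config, coefficients = calibration)

  periods <- list(training = train)
  for (y in config$test_years) {
    wy <- weather[yr %in% y, , drop = FALSE]
    if (nrow(wy) == 0) stop("no validation data for year ", y, call. = FALSE)
    periods[[as.character(y)]] <- study_period(wy, config,
                                               coefficients = calibration)
  }

  metrics <- do.call(rbind, lapply(names(periods), function(p) {
    per <- periods[[p]]
    do.call(rbind, lapply(c("original", "modified"), function(v) {
      tab <- metric_table(per$reference,
                          if (v == "original") per$originals else per$modified)
      cbind(period = p, variant = v, tab)
    }))
  }))
  rownames(metrics) <- NULL

  # validation average: arithmetic mean of per-year metrics
  test_names <- as.character(config$test_years)
  if (length(test_names) > 1) {
    test_m <- metrics[metrics$period %in% test_names, ]
    num <- c("mae", "mape", "rmse", "nse", "r2")
    avg <- stats::aggregate(test_m[num],
                            by = test_m[c("variant", "model_id")], mean)
    avg <- cbind(period = "validation_avg", avg[c("variant", "model_id")],
                 avg[num],
                 mape_class = classify_mape(avg$mape),
                 nse_class = classify_nse(avg$nse),
                 acceptable_mae = avg$mae < 0.52,
                 acceptable_rmse = avg$rmse < 0.50,
                 acceptable_nse = avg$nse > 0.75)
    metrics <- rbind(metrics, avg[names(metrics)])
  }

  monthly <- list()
  for (p in names(periods)) {
    for (v in c("original", "modified")) {
      monthly[[paste(p, v, sep = "_")]] <-
        monthly_table(periods[[p]], v, config$season_months)
    }
  }

  structure(list(calibration = calibration, metrics = metrics,
                 monthly = monthly, series = periods, config = config),
            class = "et0_report")
}

#' @export
print.et0_report <- function(x, ...) {
  cat("ET0 calibration study report\n")
  cat("\nCalibration coefficients (ET0 = a * original + b):\n")
  cf <- x$calibration
  cf[c("a", "b", "sse", "r2")] <- lapply(cf[c("a", "b", "sse", "r2")],
                                         round, 4)
  print(cf, row.names = FALSE)
  cat("\nMetrics (2 dp):\n")
  m <- x$metrics
  m[c("mae", "mape", "rmse", "nse", "r2")] <-
    lapply(m[c("mae", "mape", "rmse", "nse", "r2")], round, 2)
  print(m[c("period", "variant", "model_id", "mae", "mape", "rmse",
            "nse", "r2", "mape_class", "nse_class")], row.names = FALSE)
  invisible(x)
}

#' Render a study report to files
#'
#' Writes `calibration.csv`, `metrics.csv`, one `monthly_<period>_<variant>.csv`
#' per table, a machine-readable `report.json` (full precision) and a
#' human-readable `summary.txt` (2 dp). Output is deterministic: the same
#' report produces byte-identical files.
#'
#' @param report An `et0_report` from [run_study()].
#' @param out_dir Output directory (created if absent).
#' @param formats Subset of `c("csv", "json", "txt")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, out_dir, formats = c("csv", "json", "txt")) {
  stopifnot(inherits(report, "et0_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("csv" %in% formats) {
    p <- file.path(out_dir, "calibration.csv")
    utils::write.csv(report$calibration, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    p <- file.path(out_dir, "metrics.csv")
    utils::write.csv(report$metrics, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    for (nm in names(report$monthly)) {
      p <- file.path(out_dir, paste0("monthly_", nm, ".csv"))
      utils::write.csv(round(report$monthly[[nm]], 2), p, quote = FALSE)
      written <- c(written, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(calibration = report$calibration, metrics = report$metrics,
           monthly = lapply(report$monthly, function(tb)
             cbind(month = rownames(tb), tb))),
      p, dataframe = "rows", digits = NA, pretty = TRUE)
    written <- c(written, p)
  }
  if ("txt" %in% formats) {
    p <- file.path(out_dir, "summary.txt")
    con <- file(p, "w")
    sink(con)
    print(report)
    sink()
    close(con)
    written <- c(written, p)
  }
  invisible(written)
}
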