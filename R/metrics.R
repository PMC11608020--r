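# Goodness-of-fit statistics for ET0 estimates (MAE, MAPE, RMSE, NSE, R2)
# and the categorical accuracy / acceptability conventions used in the
# evapotranspiration-modelling literature.

#' Evaluate an estimated ET0 series against the reference
#'
#' Computes, over date-aligned pairs (X = actual, Y = estimated):
#' \itemize{
#'   \item MAE  = mean(|X - Y|), mm day-1
#'   \item MAPE = mean(|(X - Y)/X|) * 100, percent
#'   \item RMSE = sqrt(mean((X - Y)^2)), mm day-1
#'   \item NSE  = 1 - sum((X - Y)^2) / sum((X - mean(X))^2)
#'   \item R2   = squared Pearson correlation of X and Y
#' }
#' R2 deliberately uses the squared-correlation form rather than
#' `1 - SSE/SST`, so an uncalibrated model can combine high R2 with
#' negative NSE (strong correlation, large bias).
#'
#' @param actual Reference ET0, [et0_series()] or numeric; all values must be
#'   non-zero (MAPE) and non-constant (NSE, R2).
#' @param estimated Estimated ET0, date-aligned with `actual`.
#' @return An `et0_metrics` list: `mae`, `mape`, `rmse`, `nse`, `r2`, `n`,
#'   the classes from [classify_mape()] / [classify_nse()] and the
#'   [acceptability_flags()].
#' @export
evaluate <- function(actual, estimated) {
  al <- align_series(actual, estimated)
  x <- al$x
  y <- al$y
  n <- length(x)
  if (n < 2) stop("evaluation needs at least 2 paired days", call. = FALSE)
  if (any(x == 0)) {
    stop("MAPE undefined: actual series contains zero values", call. = FALSE)
  }
  sst <- sum((x - mean(x))^2)
  if (sst == 0) {
    stop("NSE and R2 undefined: actual series has zero variance", call. = FALSE)
  }
  e <- x - y
  mae <- mean(abs(e))
  mape <- mean(abs(e / x)) * 100
  rmse <- sqrt(mean(e^2))
  nse <- 1 - sum(e^2) / sst
  r2 <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)^2
  m <- structure(list(mae = mae, mape = mape, rmse = rmse, nse = nse,
                      r2 = r2, n = n,
                      mape_class = classify_mape(mape),
                      nse_class = classify_nse(nse)),
                 class = "et0_metrics")
  c_flags <- acceptability_flags(m)
  m[names(c_flags)] <- c_flags
  m
}

#' Accuracy class from MAPE
#'
#' Bands: excellent `[0, 10)`, good `[10, 20)`, reasonable `[20, 50]`,
#' inaccurate `(50, Inf)`. The published prose ranges overlap at their
#' endpoints ("10-20", "20-50"); the half-open convention here is fixed and
#' documented, and no published value falls on a boundary.
#'
#' @param mape Mean absolute percentage error, percent, non-negative.
#' @return Character class, vectorised.
#' @export
classify_mape <- function(mape) {
  if (any(mape < 0)) stop("MAPE must be non-negative", call. = FALSE)
  ifelse(mape < 10, "excellent",
         ifelse(mape < 20, "good",
                ifelse(mape <= 50, "reasonable", "inaccurate")))
}

#' Accuracy class from Nash-Sutcliffe efficiency
#'
#' Bands: good `(0.75, 1]`, satisfying `[0.36, 0.75]`, less satisfactory
#' below 0.36.
#'
#' @param nse Nash-Sutcliffe efficiency, at most 1.
#' @return Character class, vectorised.
#' @export
classify_nse <- function(nse) {
  if (any(nse > 1)) stop("NSE cannot exceed 1", call. = FALSE)
  ifelse(nse > 0.75, "good",
         ifelse(nse >= 0.36, "satisfying", "less_satisfactory"))
}

#' Acceptability thresholds for daily ET0 estimates
#'
#' Strict inequalities per the conventional limits: MAE below 0.52 mm day-1,
#' RMSE below 0.50 mm day-1, NSE above 0.75.
#'
#' @param m An `et0_metrics` object or list with `mae`, `rmse`, `nse`.
#' @return Named logical list: `acceptable_mae`, `acceptable_rmse`,
#'   `acceptable_nse`.
#' @export
acceptability_flags <- function(m) {
  list(acceptable_mae = m$mae < 0.52,
       acceptable_rmse = m$rmse < 0.50,
       acceptable_nse = m$nse > 0.75)
}

#' @export
print.et0_metrics <- function(x, ...) {
  cat(sprintf(
    "ET0 metrics (n = %d)\n  MAE  = %.2f mm/day%s\n  MAPE = %.2f %% [%s]\n  RMSE = %.2f mm/day%s\n  NSE  = %.2f [%s]%s\n  R2   = %.2f\n",
    x$n, x$mae, if (x$acceptable_mae) " (acceptable)" else "",
    x$mape, x$mape_class,
    x$rmse, if (x$acceptable_rmse) " (acceptable)" else "",
    x$nse, gsub("_", " ", x$nse_class),
    if (x$acceptable_nse) " (acceptable)" else "",
    x$r2))
  invisible(x)
}

#' Tabulate metrics for several models
#'
#' Convenience wrapper producing one row per model in the style of a
#' published performance table (metrics plus classification columns).
#'
#' @param reference Reference [et0_series()].
#' @param estimates Named list of estimated series.
#' @return Data frame: `model_id`, `mae`, `mape`, `rmse`, `nse`, `r2`,
#'   `mape_class`, `nse_class`, acceptability flags.
#' @export
metric_table <- function(reference, estimates) {
  rows <- lapply(names(estimates), function(m) {
    s <- evaluate(reference, estimates[[m]])
    data.frame(model_id = m, mae = s$mae, mape = s$mape, rmse = s$rmse,
               nse = s$nse, r2 = s$r2, mape_class = s$mape_class,
               nse_class = s$nse_class,
               acceptable_mae = s$acceptable_mae,
               acceptable_rmse = s$acceptable_rmse,
               acceptable_nse = s$acceptable_nse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
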