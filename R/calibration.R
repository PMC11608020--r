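# Least-squares calibration of mass-transfer ET0 estimates against the
# FAO-56 PM reference. The original study minimised the calibration SSE
# with an iterative spreadsheet solver; ordinary least squares minimises
# the identical objective in closed form, so OLS is used here.

# align two et0_series (or accept plain numeric vectors of equal length)
align_series <- function(actual, estimated) {
  if (inherits(actual, "et0_series") && inherits(estimated, "et0_series")) {
    if (nrow(actual) != nrow(estimated) ||
        any(actual$date != estimated$date)) {
      stop("series are not date-aligned", call. = FALSE)
    }
    list(x = actual$et0, y = estimated$et0)
  } else {
    x <- if (inherits(actual, "et0_series")) actual$et0 else as.numeric(actual)
    y <- if (inherits(estimated, "et0_series")) estimated$et0 else as.numeric(estimated)
    if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
    list(x = x, y = y)
  }
}

#' Fit linear calibration coefficients for one model
#'
#' Ordinary least squares of the reference (FAO-56 PM) ET0 on the model's
#' original estimates: finds `(a, b)` minimising
#' `sum((actual - (a * estimated + b))^2)` — the modified equation is then
#' `ET0 = a * [original model] + b`. The reference series is the dependent
#' variable and the model estimate the regressor.
#'
#' @param actual Reference ET0 series (FAO-56 PM), [et0_series()] or numeric.
#' @param estimated Original model ET0 series, date-aligned with `actual`.
#' @param model_id Optional label; taken from `estimated`'s attribute when
#'   absent.
#' @return An `et0_calibration` list: `model_id`, `a`, `b`, `n`, `sse`, `r2`.
#' @export
fit_linear_calibration <- function(actual, estimated, model_id = NULL) {
  if (is.null(model_id) && inherits(estimated, "et0_series")) {
    model_id <- attr(estimated, "method")
  }
  al <- align_series(actual, estimated)
  x <- al$x   # reference (dependent)
  y <- al$y   # model estimate (regressor)
  n <- length(x)
  if (n < 3) stop("calibration needs at least 3 paired days", call. = FALSE)
  if (stats::var(y) == 0) {
    stop("degenerate fit: estimated series has zero variance", call. = FALSE)
  }
  a <- stats::cov(x, y) / stats::var(y)
  b <- mean(x) - a * mean(y)
  resid <- x - (a * y + b)
  sse <- sum(resid^2)
  sst <- sum((x - mean(x))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(model_id = model_id %||% NA_character_,
                 a = a, b = b, n = n, sse = sse, r2 = r2),
            class = "et0_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.et0_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration%s: ET0 = %.4f * [original] + %.4f  (n = %d, R2 = %.4f)\n",
              if (is.na(x$model_id)) "" else paste0(" [", x$model_id, "]"),
              x$a, x$b, x$n, x$r2))
  invisible(x)
}

#' Calibrate all six mass-transfer models against one reference series
#'
#' @param reference FAO-56 PM [et0_series()].
#' @param estimates Named list of [et0_series()], one per model in
#'   [mass_transfer_models()]; all must be present and date-aligned with the
#'   reference.
#' @return Data frame with one row per model (ordered by `model_id`):
#'   `model_id`, `a`, `b`, `n`, `sse`, `r2`.
#' @export
calibrate_all_models <- function(reference, estimates) {
  wanted <- sort(mass_transfer_models())
  missing_models <- setdiff(wanted, names(estimates))
  if (length(missing_models)) {
    stop("missing model series: ", paste(missing_models, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(wanted, function(m) {
    fit <- fit_linear_calibration(reference, estimates[[m]], model_id = m)
    data.frame(model_id = m, a = fit$a, b = fit$b, n = fit$n,
               sse = fit$sse, r2 = fit$r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a coefficient table as delimited text
#'
#' Writes `model_id, a, b` (full precision) to `path`, mirroring the layout
#' of a published calibration-coefficient table.
#'
#' @param coefficients Data frame from [calibrate_all_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefficients, path) {
  utils::write.csv(coefficients[c("model_id", "a", "b")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
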