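# Published reference values for the Van Lake basin calibration study
# (Edremit station, 1669 m, 38.47 N; April-October, 2012-2020). Stored as
# plain constructors so downstream code and the acceptance report can apply
# the published coefficient tables without re-deriving them from the raw
# station archive, which is not redistributable.

#' Published calibration coefficients for the Van Lake basin
#'
#' Slope `a` and intercept `b` of the modified equation
#' `ET0 = a * [original model] + b` fitted against FAO-56 PM on the
#' 2012-2020 multi-year-average series at the Van Edremit station.
#'
#' @return Data frame: `model_id`, `a`, `b`.
#' @export
van_calibration_coefficients <- function() {
  data.frame(
    model_id = c("dalton", "rohwer", "penman", "romanenko", "wmo", "mahringer"),
    a = c(0.5457, 0.5286, 0.4555, 0.5220, 0.7402, 0.6372),
    b = c(1.3459, 1.3849, 1.5061, 1.6315, 1.5715, 1.4336),
    stringsAsFactors = FALSE
  )
}

#' Published monthly-mean ET0 of the original models at Van (2012-2020)
#'
#' April-October monthly means of daily ET0 (mm day-1) for the FAO-56 PM
#' reference and the six original mass-transfer models.
#'
#' @return Data frame with a `month` column (Apr..Oct) and one column per
#'   model.
#' @export
van_monthly_et0 <- function() {
  data.frame(
    month     = c("Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct"),
    fao56pm   = c(2.49, 3.57, 4.91, 5.87, 5.58, 4.36, 2.56),
    dalton    = c(2.14, 3.39, 5.71, 8.11, 8.17, 6.04, 3.10),
    wmo       = c(1.41, 2.35, 3.94, 5.53, 5.49, 4.05, 2.13),
    mahringer = c(1.75, 2.83, 4.78, 6.75, 6.76, 4.99, 2.57),
    penman    = c(2.36, 3.89, 6.54, 9.20, 9.16, 6.77, 3.54),
    rohwer    = c(2.16, 3.47, 5.84, 8.27, 8.30, 6.13, 3.17),
    romanenko = c(2.31, 3.29, 5.17, 7.01, 7.17, 5.71, 3.11),
    stringsAsFactors = FALSE
  )
}
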