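# ET0 estimators: the FAO-56 Penman-Monteith reference and six empirical
# mass-transfer models, plus the dispatcher that resolves each model's unit
# dialect (hPa vs mmHg for VPD, m/s vs miles/day for wind).

#' Registry of supported ET0 models
#'
#' Each mass-transfer model declares the unit dialect of its vapour pressure
#' deficit and wind speed terms. The dispatcher [compute_et0()] converts from
#' the internal kPa / m s-1 representation; callers never pre-convert.
#'
#' @return Data frame with columns `model_id`, `vpd_unit`, `wind_unit`.
#' @export
model_registry <- function() {
  data.frame(
    model_id  = c("fao56pm", "dalton", "rohwer", "penman",
                  "romanenko", "wmo", "mahringer"),
    vpd_unit  = c("kPa", "hPa", "mmHg", "mmHg", "n/a", "hPa", "hPa"),
    wind_unit = c("m_s", "m_s", "m_s", "miles_day", "n/a", "m_s", "m_s"),
    stringsAsFactors = FALSE
  )
}

#' @rdname model_registry
#' @export
mass_transfer_models <- function() {
  setdiff(model_registry()$model_id, "fao56pm")
}

#' FAO-56 Penman-Monteith daily reference evapotranspiration
#'
#' `ET0 = (0.408 Delta (Rn - G) + gamma (900/(T+273)) u2 (es - ea)) /
#'        (Delta + gamma (1 + 0.34 u2))`
#'
#' @param delta Slope of the saturation curve, kPa degC-1.
#' @param gamma Psychrometric constant, kPa degC-1.
#' @param rn Net radiation, MJ m-2 day-1.
#' @param g Soil heat flux, MJ m-2 day-1 (0 at daily steps).
#' @param tmean Daily mean air temperature, degC.
#' @param u2 Wind speed at 2 m, m s-1.
#' @param es,ea Mean saturation and actual vapour pressure, kPa.
#' @return ET0 in mm day-1.
#' @export
et0_fao56_pm <- function(delta, gamma, rn, g, tmean, u2, es, ea) {
  if (any(delta <= 0) || any(gamma <= 0)) {
    stop("`delta` and `gamma` must be positive", call. = FALSE)
  }
  if (any(u2 < 0)) stop("`u2` must be non-negative", call. = FALSE)
  num <- 0.408 * delta * (rn - g) + gamma * (900 / (tmean + 273)) * u2 * (es - ea)
  num / (delta + gamma * (1 + 0.34 * u2))
}

#' Mass-transfer ET0 models (original equations)
#'
#' The six empirical aerodynamic estimators. Note the unit dialects:
#' `vpd` is in hPa for Dalton, WMO and Mahringer but in mmHg for Rohwer and
#' Penman; wind is m s-1 except for Penman (miles day-1); Romanenko uses
#' only mean temperature and mean relative humidity.
#'
#' @param u2 Wind speed at 2 m, m s-1 (non-negative).
#' @param vpd Vapour pressure deficit in the model's dialect (hPa or mmHg).
#' @return ET0 in mm day-1.
#' @name mass_transfer
NULL

#' @rdname mass_transfer
#' @export
et0_dalton <- function(u2, vpd) {
  if (any(u2 < 0)) stop("`u2` must be non-negative", call. = FALSE)
  (0.3648 + 0.07223 * u2) * vpd
}

#' @rdname mass_transfer
#' @export
et0_rohwer <- function(u2, vpd) {
  if (any(u2 < 0)) stop("`u2` must be non-negative", call. = FALSE)
  0.44 * (1 + 0.27 * u2) * vpd
}

#' @rdname mass_transfer
#' @param u2_miles Daily wind run in miles day-1 (Penman only).
#' @export
et0_penman <- function(u2_miles, vpd) {
  if (any(u2_miles < 0)) stop("wind run must be non-negative", call. = FALSE)
  0.35 * (1 + 0.98 / 100 * u2_miles) * vpd
}

#' @rdname mass_transfer
#' @param tmean Daily mean air temperature, degC (Romanenko only).
#' @param rhmean Daily mean relative humidity, percent (Romanenko only).
#' @export
et0_romanenko <- function(tmean, rhmean) {
  if (any(rhmean < 0 | rhmean > 100)) {
    stop("`rhmean` must lie in [0, 100]", call. = FALSE)
  }
  0.00006 * (tmean + 25)^2 * (100 - rhmean)
}

#' @rdname mass_transfer
#' @export
et0_wmo <- function(u2, vpd) {
  if (any(u2 < 0)) stop("`u2` must be non-negative", call. = FALSE)
  (0.1298 + 0.0934 * u2) * vpd
}

#' @rdname mass_transfer
#' @export
et0_mahringer <- function(u2, vpd) {
  if (any(u2 < 0)) stop("`u2` must be non-negative", call. = FALSE)
  0.15072 * sqrt(3.60 * u2) * vpd
}

#' Construct a dated ET0 series
#'
#' @param dates Vector of `Date`s, strictly increasing.
#' @param values ET0 values, mm day-1, one per date.
#' @param method Model id from [model_registry()].
#' @param variant `"reference"`, `"original"` or `"modified"`.
#' @return Data frame of class `et0_series` with columns `date`, `et0` and
#'   attributes `method` and `variant`.
#' @export
et0_series <- function(dates, values, method, variant = "original") {
  dates <- as.Date(dates)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` lengths differ", call. = FALSE)
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("`dates` must be strictly increasing", call. = FALSE)
  }
  if (!method %in% model_registry()$model_id) {
    stop("unknown model id: ", method, call. = FALSE)
  }
  variant <- match.arg(variant, c("original", "modified", "reference"))
  structure(data.frame(date = dates, et0 = as.numeric(values)),
            method = method, variant = variant,
            class = c("et0_series", "data.frame"))
}

#' Compute an ET0 series for one model from daily weather
#'
#' The dispatcher: derives the vapour-pressure chain (es, ea, VPD) from the
#' daily temperature and humidity extremes, converts VPD and wind to the
#' model's declared dialect, and evaluates the model. For `"fao56pm"` it
#' additionally computes the radiation and psychrometric terms from the
#' station metadata. Supplying calibration coefficients applies the linear
#' mapping `a * ET0 + b` and labels the series `"modified"`.
#'
#' @param weather Validated weather data frame (see [as_weather()]).
#' @param model Model id from [model_registry()].
#' @param station [station_meta()]; required for `"fao56pm"`, ignored by the
#'   mass-transfer models except for the anemometer-height wind correction.
#' @param g Soil heat flux, MJ m-2 day-1; 0 at daily steps.
#' @param coefficients Optional list or named vector with `a` and `b`.
#' @return An [et0_series()].
#' @export
compute_et0 <- function(weather, model, station = NULL, g = 0,
                        coefficients = NULL) {
  weather <- as_weather(weather)
  reg <- model_registry()
  if (!model %in% reg$model_id) {
    stop("unknown model id: ", model, "; known: ",
         paste(reg$model_id, collapse = ", "), call. = FALSE)
  }
  u2 <- weather$u2
  if (!is.null(station) && station$anemometer_height != 2) {
    u2 <- adjust_wind_to_2m(u2, station$anemometer_height)
  }
  es <- mean_saturation_vapour_pressure(weather$tmax, weather$tmin)
  ea <- actual_vapour_pressure(weather$tmax, weather$tmin,
                               weather$rhmax, weather$rhmin)
  vpd <- vapour_pressure_deficit(es, ea)

  values <- switch(
    model,
    fao56pm = {
      if (is.null(station)) {
        stop("`station` is required for the FAO-56 PM model", call. = FALSE)
      }
      doy <- as.integer(format(weather$date, "%j"))
      delta <- slope_saturation_curve(weather$tmean)
      gamma <- psychrometric_constant(station$elevation)
      rn <- net_radiation(weather$rs, weather$tmax, weather$tmin, ea,
                          station, doy)
      et0_fao56_pm(delta, gamma, rn, g, weather$tmean, u2, es, ea)
    },
    dalton    = et0_dalton(u2, convert_pressure(vpd, "hPa")),
    rohwer    = et0_rohwer(u2, convert_pressure(vpd, "mmHg")),
    penman    = et0_penman(convert_wind_to_miles_per_day(u2),
                           convert_pressure(vpd, "mmHg")),
    romanenko = et0_romanenko(weather$tmean, weather$rhmean),
    wmo       = et0_wmo(u2, convert_pressure(vpd, "hPa")),
    mahringer = et0_mahringer(u2, convert_pressure(vpd, "hPa"))
  )

  variant <- if (model == "fao56pm") "reference" else "original"
  if (!is.null(coefficients)) {
    values <- apply_linear_calibration(values, coefficients[["a"]],
                                       coefficients[["b"]])
    variant <- "modified"
  }
  et0_series(weather$date, values, method = model, variant = variant)
}

#' Apply a linear calibration mapping
#'
#' `a * x + b`, elementwise. Because the mapping is affine it commutes with
#' arithmetic averaging, so monthly and seasonal means of a modified series
#' equal the mapping applied to the means of the original series.
#'
#' @param x Numeric vector or [et0_series()] of original ET0 values.
#' @param a Slope (dimensionless).
#' @param b Intercept, mm day-1.
#' @return Calibrated values; an `et0_series` input keeps its dates and is
#'   relabelled `variant = "modified"`.
#' @export
apply_linear_calibration <- function(x, a, b) {
  stopifnot(is.finite(a), is.finite(b))
  vals <- if (inherits(x, "et0_series")) x$et0 else x
  out <- a * vals + b
  if (any(out < 0)) {
    warning(sum(out < 0), " negative calibrated ET0 value(s); not clipped",
            call. = FALSE)
  }
  if (inherits(x, "et0_series")) {
    return(et0_series(x$date, out, method = attr(x, "method"),
                      variant = "modified"))
  }
  out
}
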