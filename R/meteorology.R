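# Thermodynamic and radiative quantities used by every ET0 model.
# All vapour pressures are kPa internally; unit conversions to the
# hPa / mmHg / miles-per-day dialects of the mass-transfer models happen
# only at the model boundary (see dialect handling in compute_et0()).

#' Saturation vapour pressure of air
#'
#' Tetens-type exponential used throughout the FAO-56 methodology:
#' `e(T) = 0.6108 * exp(17.27 * T / (T + 237.3))`.
#'
#' @param t Air temperature in degrees Celsius. Vectorised.
#' @return Saturation vapour pressure in kPa.
#' @examples
#' saturation_vapour_pressure(20) # 2.3383 kPa
#' @export
saturation_vapour_pressure <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric air temperature in degC", call. = FALSE)
  }
  if (any(t <= -237.3)) {
    stop("air temperature at or below -237.3 degC is outside the formula domain",
         call. = FALSE)
  }
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Mean saturation vapour pressure from daily extremes
#'
#' Daily mean `es` is the average of the saturation pressures at the daily
#' maximum and minimum temperatures, not the saturation pressure at the mean
#' temperature (the curve is convex).
#'
#' @param tmax,tmin Daily maximum and minimum air temperature, degC.
#' @return Mean saturation vapour pressure `es` in kPa.
#' @export
mean_saturation_vapour_pressure <- function(tmax, tmin) {
  if (any(tmin > tmax)) stop("`tmin` must not exceed `tmax`", call. = FALSE)
  (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
}

#' Actual vapour pressure from temperature and humidity extremes
#'
#' `ea = (es(tmin) * RHmax/100 + es(tmax) * RHmin/100) / 2`: the daily
#' maximum humidity is paired with the coolest part of the day and the
#' minimum humidity with the warmest.
#'
#' @param tmax,tmin Daily temperature extremes, degC.
#' @param rhmax,rhmin Daily relative-humidity extremes, percent in \[0, 100\].
#' @return Actual vapour pressure `ea` in kPa.
#' @export
actual_vapour_pressure <- function(tmax, tmin, rhmax, rhmin) {
  if (any(rhmax < 0 | rhmax > 100 | rhmin < 0 | rhmin > 100)) {
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  }
  (saturation_vapour_pressure(tmin) * rhmax / 100 +
     saturation_vapour_pressure(tmax) * rhmin / 100) / 2
}

#' Vapour pressure deficit
#'
#' `VPD = es - ea`. A negative deficit indicates physically inconsistent
#' inputs; it is propagated (with a warning) rather than clipped so that
#' data errors stay visible downstream.
#'
#' @param es Mean saturation vapour pressure, kPa.
#' @param ea Actual vapour pressure, kPa.
#' @return Vapour pressure deficit in kPa (may be negative, with warning).
#' @export
vapour_pressure_deficit <- function(es, ea) {
  if (any(es < 0) || any(ea < 0)) {
    stop("vapour pressures must be non-negative", call. = FALSE)
  }
  vpd <- es - ea
  if (any(vpd < 0)) {
    warning(sum(vpd < 0), " negative VPD value(s): ea exceeds es; ",
            "propagated unclipped", call. = FALSE)
  }
  vpd
}

#' Slope of the saturation vapour pressure curve
#'
#' `Delta = 4098 * es(T) / (T + 237.3)^2`, evaluated at mean air temperature.
#'
#' @param tmean Daily mean air temperature, degC.
#' @return Slope in kPa per degC.
#' @export
slope_saturation_curve <- function(tmean) {
  4098 * saturation_vapour_pressure(tmean) / (tmean + 237.3)^2
}

#' Atmospheric pressure from elevation
#'
#' Standard-atmosphere profile `P = 101.3 * ((293 - 0.0065 z) / 293)^5.26`.
#'
#' @param elevation Station elevation, m above sea level.
#' @return Atmospheric pressure in kPa.
#' @export
atmospheric_pressure <- function(elevation) {
  101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
}

#' Psychrometric constant
#'
#' `gamma = 0.000665 * P(z)`; decreases with station elevation.
#'
#' @inheritParams atmospheric_pressure
#' @return Psychrometric constant in kPa per degC.
#' @export
psychrometric_constant <- function(elevation) {
  0.000665 * atmospheric_pressure(elevation)
}

#' Extraterrestrial radiation for daily periods
#'
#' Top-of-atmosphere solar radiation from the solar constant
#' (0.0820 MJ m-2 min-1), inverse relative earth-sun distance, solar
#' declination and sunset hour angle.
#'
#' @param latitude Latitude in decimal degrees, positive north.
#' @param day_of_year Integer day of year, 1-366.
#' @return Ra in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop("`day_of_year` must be in 1..366", call. = FALSE)
  }
  phi <- latitude * pi / 180
  j <- day_of_year
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  dec <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  x <- -tan(phi) * tan(dec)
  # polar day / night: clamp the sunset hour angle
  ws <- acos(pmin(pmax(x, -1), 1))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Clear-sky solar radiation
#'
#' `Rso = (0.75 + 2e-5 z) * Ra`; the upper envelope for measured solar
#' radiation at a station of elevation `z`.
#'
#' @inheritParams extraterrestrial_radiation
#' @param elevation Station elevation, m.
#' @return Rso in MJ m-2 day-1.
#' @export
clear_sky_radiation <- function(latitude, day_of_year, elevation) {
  (0.75 + 2e-5 * elevation) * extraterrestrial_radiation(latitude, day_of_year)
}

#' Daily net radiation at the reference crop surface
#'
#' Net shortwave minus net longwave:
#' `Rns = (1 - albedo) * Rs` with grass albedo 0.23, and
#' `Rnl = sigma * (Tmax,K^4 + Tmin,K^4)/2 * (0.34 - 0.14 sqrt(ea)) *
#' (1.35 Rs/Rso - 0.35)` with `sigma = 4.903e-9` MJ K-4 m-2 day-1.
#' The relative shortwave ratio `Rs/Rso` is capped at 1 for robustness to
#' measurement noise on clear days.
#'
#' @param rs Measured solar radiation, MJ m-2 day-1.
#' @param tmax,tmin Daily temperature extremes, degC.
#' @param ea Actual vapour pressure, kPa.
#' @param station A [station_meta()] object (latitude and elevation used).
#' @param day_of_year Integer day of year.
#' @param albedo Surface albedo; 0.23 for the reference grass crop.
#' @return Net radiation Rn in MJ m-2 day-1.
#' @export
net_radiation <- function(rs, tmax, tmin, ea, station, day_of_year,
                          albedo = 0.23) {
  if (any(rs < 0)) stop("`rs` must be non-negative", call. = FALSE)
  rso <- clear_sky_radiation(station$latitude, day_of_year, station$elevation)
  if (any(rso <= 0 & rs > 0)) {
    stop("positive solar radiation during polar night (Rso = 0)", call. = FALSE)
  }
  rns <- (1 - albedo) * rs
  ratio <- ifelse(rso > 0, pmin(rs / rso, 1), 0)
  sigma <- 4.903e-9
  rnl <- sigma * (((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2) *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * ratio - 0.35)
  rns - rnl
}

#' Convert a pressure in kPa to a mass-transfer model dialect
#'
#' @param value Pressure in kPa.
#' @param target `"hPa"` or `"mmHg"` (760 mmHg = 101.325 kPa).
#' @return Pressure in the target unit.
#' @export
convert_pressure <- function(value, target = c("hPa", "mmHg")) {
  if (any(!is.finite(value))) stop("`value` must be finite", call. = FALSE)
  target <- match.arg(target)
  switch(target,
         hPa  = value * 10,
         mmHg = value * 760 / 101.325)
}

#' Convert wind speed to miles per day
#'
#' The statute mile (1609.344 m) is used; the historical literature on the
#' Penman wind function does not define its mile, so the length is exposed
#' as an argument.
#'
#' @param u Wind speed in m s-1, non-negative.
#' @param mile_m Length of one mile in metres.
#' @return Wind run in miles day-1.
#' @export
convert_wind_to_miles_per_day <- function(u, mile_m = 1609.344) {
  if (any(u < 0)) stop("wind speed must be non-negative", call. = FALSE)
  u * 86400 / mile_m
}

#' Adjust wind speed measured at another height to 2 m
#'
#' Logarithmic profile over short grass:
#' `u2 = uz * 4.87 / log(67.8 * zm - 5.42)`. Pass-through when `zm == 2`.
#'
#' @param uz Wind speed measured at height `zm`, m s-1.
#' @param zm Measurement height, m (> 0.08 so the log argument is positive).
#' @return Wind speed at 2 m, m s-1.
#' @export
adjust_wind_to_2m <- function(uz, zm) {
  if (any(zm <= 5.42 / 67.8)) stop("anemometer height too low", call. = FALSE)
  if (any(zm == 2)) return(uz)
  uz * 4.87 / log(67.8 * zm - 5.42)
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' Spreadsheet-compatible skewness,
#' `n/((n-1)(n-2)) * sum(((x - mean)/s)^3)` with `s` the sample standard
#' deviation — the definition used by common spreadsheet software, so
#' summary tables match values computed there.
#'
#' @param x Numeric vector, length >= 3, non-zero variance.
#' @return Skewness coefficient (dimensionless).
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("skewness undefined for zero-variance series", call. = FALSE)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Station metadata
#'
#' @param latitude Decimal degrees, positive north, in \[-90, 90\].
#' @param elevation Metres above sea level (> -430, the lowest land surface).
#' @param anemometer_height Wind measurement height in m; wind is corrected
#'   to 2 m with [adjust_wind_to_2m()] when this differs from 2.
#' @return A `station_meta` list.
#' @examples
#' # the Van Edremit station: 38 deg 28 min N, 1669 m
#' van_station()
#' @export
station_meta <- function(latitude, elevation, anemometer_height = 2) {
  stopifnot(is.numeric(latitude), is.numeric(elevation))
  if (latitude < -90 || latitude > 90) stop("latitude outside [-90, 90]", call. = FALSE)
  if (elevation <= -430) stop("elevation below lowest land surface", call. = FALSE)
  if (anemometer_height <= 0) stop("anemometer height must be positive", call. = FALSE)
  structure(list(latitude = latitude, elevation = elevation,
                 anemometer_height = anemometer_height),
            class = "station_meta")
}

#' @rdname station_meta
#' @export
van_station <- function() {
  station_meta(latitude = 38 + 28 / 60, elevation = 1669)
}

# required columns of a daily weather data frame
weather_columns <- function() {
  c("date", "tmax", "tmin", "tmean", "rhmax", "rhmin", "rhmean", "rs", "u2")
}

# logical vector: does each row satisfy the daily-record invariants?
weather_row_ok <- function(df) {
  num <- df[setdiff(weather_columns(), "date")]
  finite <- Reduce(`&`, lapply(num, is.finite))
  finite &
    df$tmin <= df$tmean & df$tmean <= df$tmax &
    df$rhmin >= 0 & df$rhmin <= df$rhmean & df$rhmean <= df$rhmax &
    df$rhmax <= 100 &
    df$rs >= 0 & df$u2 >= 0
}

#' Validate a daily weather data frame
#'
#' Checks the column schema and the per-row physical invariants
#' (`tmin <= tmean <= tmax`, humidities ordered within \[0, 100\],
#' non-negative radiation and wind). Offending rows are dropped with a
#' warning giving the count.
#'
#' @param df Data frame with columns
#'   `date, tmax, tmin, tmean, rhmax, rhmin, rhmean, rs, u2`.
#' @return The validated data frame (class `et0_weather`), invalid rows
#'   removed, ordered by date.
#' @export
as_weather <- function(df) {
  missing_cols <- setdiff(weather_columns(), names(df))
  if (length(missing_cols)) {
    stop("weather data missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[weather_columns()]
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) {
    bad <- which(is.na(df$date))
    stop("unparseable date(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ok <- weather_row_ok(df)
  if (any(!ok)) {
    warning("dropped ", sum(!ok), " row(s) violating daily-record invariants",
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid weather rows remain", call. = FALSE)
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("et0_weather", "data.frame")
  df
}
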