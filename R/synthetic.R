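# Seeded synthetic daily-weather generator. Emulates a high-altitude
# semi-arid April-October growing season: each variable is a sinusoidal
# seasonal cycle plus skewed noise tuned so that the pooled mean, SD and
# skewness match configured targets (defaults: the 2012-2020 Van Edremit
# station climatology). Only the marginal structure plus one documented
# T-RH anti-correlation is modelled; see the methods vignette.

# solve the skew-normal shape delta from a target skewness
# |g| = (4-pi)/2 * (d*sqrt(2/pi))^3 / (1 - 2 d^2/pi)^(3/2), d in (0,1)
sn_delta_from_skew <- function(skew) {
  g <- abs(skew)
  if (g >= 0.9952) {
    stop("skew-normal family cannot reach |skewness| >= 0.9952", call. = FALSE)
  }
  if (g < 1e-12) return(0)
  f <- function(d) {
    (4 - pi) / 2 * (d * sqrt(2 / pi))^3 / (1 - 2 * d^2 / pi)^1.5 - g
  }
  d <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  sign(skew) * d
}

# skew-normal deviates with exact target mean/sd and (population) skewness
rskewnorm <- function(n, mean = 0, sd = 1, skew = 0) {
  d <- sn_delta_from_skew(skew)
  if (d == 0) return(stats::rnorm(n, mean, sd))
  omega <- sd / sqrt(1 - 2 * d^2 / pi)
  xi <- mean - omega * d * sqrt(2 / pi)
  z0 <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  xi + omega * (d * abs(z0) + sqrt(1 - d^2) * z1)
}

# shifted lognormal matching (mean, sd, skew); used for wind, whose target
# skewness (1.41) exceeds the skew-normal bound
rshifted_lognormal <- function(n, mean, sd, skew) {
  if (skew <= 0) stop("shifted lognormal requires positive skew", call. = FALSE)
  f <- function(sigma) {
    w <- exp(sigma^2)
    (w + 2) * sqrt(w - 1) - skew
  }
  sigma <- stats::uniroot(f, c(1e-6, 3), tol = 1e-10)$root
  w <- exp(sigma^2)
  s <- sd / sqrt((w - 1) * w)
  shift <- mean - s * sqrt(w)
  shift + s * exp(stats::rnorm(n, 0, sigma))
}

default_targets <- function() {
  list(
    tmean  = list(mean = 16.42, sd = 5.12, skew = -0.32, min = 4.44,  max = 23.26),
    rhmean = list(mean = 53.98, sd = 8.90, skew = 0.49,  min = 39.83, max = 75.39),
    rs     = list(mean = 20.15, sd = 3.53, skew = -0.32, min = 11.88, max = 24.88),
    u2     = list(mean = 2.65,  sd = 0.77, skew = 1.41,  min = 1.48,  max = 6.30)
  )
}

#' Configuration for the synthetic weather generator
#'
#' Defaults emulate the April-October 2012-2020 daily climatology of the
#' Van Edremit station (1669 m, 38.47 N): mean air temperature 16.42 degC
#' (SD 5.12, skew -0.32), mean relative humidity 53.98 % (SD 8.90),
#' solar radiation 20.15 MJ m-2 day-1 and 2-m wind 2.65 m s-1 (skew 1.41).
#'
#' @param start,end Season window (same calendar year); defaults
#'   April 1 - October 31.
#' @param station [station_meta()]; bounds the generated solar radiation by
#'   the station's clear-sky envelope.
#' @param targets Per-variable list (`tmean`, `rhmean`, `rs`, `u2`) of
#'   `mean`, `sd`, `skew`, `min`, `max`. `min`/`max` are descriptive
#'   plausibility bounds (checked against `mean`), not hard clips.
#' @param cycles Seasonal cycles: amplitude (same unit as the variable) and
#'   peak day-of-year for `tmean` and `rs`. Wind has no cycle; humidity
#'   inherits its seasonality through the T-RH coupling.
#' @param rh_t_correlation Correlation imposed between daily humidity and
#'   temperature anomalies (negative: hot days are dry days).
#' @param diurnal Mean/SD of the diurnal temperature span (degC) and
#'   relative-humidity span (%) used to derive daily extremes from means.
#' @param seed Integer RNG seed; identical seed and config give
#'   bitwise-identical output.
#' @return A `weather_gen_config` list.
#' @export
weather_gen_config <- function(start = "2012-04-01", end = "2012-10-31",
                               station = van_station(),
                               targets = default_targets(),
                               cycles = list(
                                 tmean = list(amplitude = 7.0, peak = 203),
                                 rs    = list(amplitude = 4.0, peak = 186)),
                               rh_t_correlation = -0.5,
                               diurnal = list(t_span_mean = 12, t_span_sd = 2,
                                              rh_span_mean = 30, rh_span_sd = 5),
                               seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("invalid season window", call. = FALSE)
  }
  if (format(start, "%Y") != format(end, "%Y")) {
    stop("season must lie within one calendar year", call. = FALSE)
  }
  for (v in names(targets)) {
    tg <- targets[[v]]
    if (tg$sd <= 0) stop("sd must be positive for ", v, call. = FALSE)
    if (tg$min >= tg$max) stop("min must be below max for ", v, call. = FALSE)
    if (tg$mean < tg$min || tg$mean > tg$max) {
      stop("target mean outside [min, max] for ", v, call. = FALSE)
    }
  }
  if (rh_t_correlation <= -1 || rh_t_correlation >= 1) {
    stop("rh_t_correlation must lie in (-1, 1)", call. = FALSE)
  }
  structure(list(start = start, end = end, station = station,
                 targets = targets, cycles = cycles,
                 rh_t_correlation = rh_t_correlation,
                 diurnal = diurnal, seed = seed),
            class = "weather_gen_config")
}

# centred seasonal cycle values and the residual noise parameters needed to
# hit pooled (sd, skew): variances add, and so do third central moments for
# independent components
cycle_noise_split <- function(doy, amplitude, peak, sd, skew) {
  cyc <- amplitude * cos(2 * pi * (doy - peak) / 365)
  cyc <- cyc - mean(cyc)
  v_cyc <- mean(cyc^2)
  if (v_cyc >= sd^2) {
    stop("seasonal cycle variance exceeds the target variance; ",
         "reduce the cycle amplitude", call. = FALSE)
  }
  v_noise <- sd^2 - v_cyc
  m3_target <- skew * sd^3
  m3_cycle <- mean(cyc^3)
  g_noise <- (m3_target - m3_cycle) / v_noise^1.5
  # the skew-normal family is bounded; clamp and let the pooled skewness
  # land where the family allows (documented feasibility limit)
  g_noise <- max(min(g_noise, 0.95), -0.95)
  list(cycle = cyc, noise_sd = sqrt(v_noise), noise_skew = g_noise)
}

#' Generate one season of synthetic daily weather
#'
#' Daily mean temperature is a sinusoidal seasonal cycle plus skew-normal
#' noise; humidity is anti-correlated with the temperature anomaly; solar
#' radiation is a solstice-peaked cycle plus skewed noise capped by the
#' clear-sky envelope; wind is shifted-lognormal. Daily extremes are derived
#' from the means via sampled diurnal spans. Every returned row satisfies
#' the daily-record invariants.
#'
#' @param config A [weather_gen_config()].
#' @return An `et0_weather` data frame, one row per day.
#' @export
generate_season <- function(config) {
  stopifnot(inherits(config, "weather_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dates <- seq(config$start, config$end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  tg <- config$targets

  # mean temperature: cycle + tuned skewed noise
  ts <- cycle_noise_split(doy, config$cycles$tmean$amplitude,
                          config$cycles$tmean$peak,
                          tg$tmean$sd, tg$tmean$skew)
  tmean <- tg$tmean$mean + ts$cycle +
    rskewnorm(n, 0, ts$noise_sd, ts$noise_skew)

  # humidity: correlated with the standardised temperature anomaly, plus an
  # independent skewed residual sized so pooled sd and skew hit the targets
  rho <- config$rh_t_correlation
  z_t <- (tmean - tg$tmean$mean) / tg$tmean$sd
  res_skew <- (tg$rhmean$skew - rho^3 * tg$tmean$skew) / (1 - rho^2)^1.5
  res_skew <- max(min(res_skew, 0.95), -0.95)
  rhmean <- tg$rhmean$mean + rho * tg$rhmean$sd * z_t +
    rskewnorm(n, 0, tg$rhmean$sd * sqrt(1 - rho^2), res_skew)
  rhmean <- pmin(pmax(rhmean, 1), 99)

  # solar radiation: cycle + noise, bounded by the clear-sky envelope
  rss <- cycle_noise_split(doy, config$cycles$rs$amplitude,
                           config$cycles$rs$peak,
                           tg$rs$sd, tg$rs$skew)
  rs <- tg$rs$mean + rss$cycle + rskewnorm(n, 0, rss$noise_sd, rss$noise_skew)
  rso <- clear_sky_radiation(config$station$latitude, doy,
                             config$station$elevation)
  rs <- pmin(pmax(rs, 0.1), rso)

  # wind: right-skewed, no seasonal cycle
  u2 <- rshifted_lognormal(n, tg$u2$mean, tg$u2$sd, tg$u2$skew)
  u2 <- pmax(u2, 0.05)

  # diurnal spans -> extremes
  t_span <- pmax(stats::rnorm(n, config$diurnal$t_span_mean,
                              config$diurnal$t_span_sd), 0.5)
  rh_span <- pmax(stats::rnorm(n, config$diurnal$rh_span_mean,
                               config$diurnal$rh_span_sd), 1)
  df <- data.frame(
    date = dates,
    tmax = tmean + t_span / 2,
    tmin = tmean - t_span / 2,
    tmean = tmean,
    rhmax = pmin(rhmean + rh_span / 2, 100),
    rhmin = pmax(rhmean - rh_span / 2, 0),
    rhmean = rhmean,
    rs = rs,
    u2 = u2
  )
  as_weather(df)
}

#' Generate several consecutive years of synthetic weather
#'
#' Calls [generate_season()] once per year with a per-year seed derived from
#' the configured base seed, shifting the season window to each year.
#'
#' @param config A [weather_gen_config()].
#' @param years Integer vector of calendar years.
#' @return An `et0_weather` data frame spanning all requested seasons.
#' @export
generate_weather_years <- function(config, years) {
  pieces <- lapply(seq_along(years), function(i) {
    cfg <- config
    cfg$start <- as.Date(sprintf("%d-%s", years[i], format(config$start, "%m-%d")))
    cfg$end <- as.Date(sprintf("%d-%s", years[i], format(config$end, "%m-%d")))
    cfg$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    generate_season(cfg)
  })
  out <- do.call(rbind, pieces)
  as_weather(out)
}

#' Build a paired reference/estimate dataset with known calibration truth
#'
#' Runs one mass-transfer model on the supplied weather to get the
#' "estimated" series, then constructs a pseudo-reference as
#' `a * estimated + b + N(0, noise_sd)`. Refitting the calibration on the
#' pair recovers `(a, b)` up to sampling error, which makes this the
#' parameter-recovery harness for the calibration module.
#'
#' @param records Daily weather (`et0_weather` or coercible).
#' @param model_id One of [mass_transfer_models()].
#' @param a,b True slope and intercept of the affine relation.
#' @param noise_sd Gaussian noise on the reference, mm day-1, >= 0.
#' @param seed Integer RNG seed.
#' @return List with `reference` and `estimated` [et0_series()].
#' @export
generate_model_truth <- function(records, model_id, a, b, noise_sd = 0.3,
                                 seed = 1L) {
  if (!model_id %in% mass_transfer_models()) {
    stop("unknown mass-transfer model id: ", model_id, call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  est <- compute_et0(records, model_id)
  set.seed(seed)
  ref_vals <- a * est$et0 + b + stats::rnorm(nrow(est), 0, noise_sd)
  list(reference = et0_series(est$date, ref_vals, method = "fao56pm",
                              variant = "reference"),
       estimated = est)
}

#' Per-variable summary statistics of daily weather
#'
#' Mean, sample SD, adjusted Fisher-Pearson skewness, minimum and maximum
#' for `tmean`, `rhmean`, `rs` and `u2` — the layout of a daily-climatology
#' summary table.
#'
#' @param records Daily weather data frame.
#' @return Data frame with one row per variable.
#' @export
summary_statistics <- function(records) {
  if (NROW(records) == 0) stop("empty weather records", call. = FALSE)
  vars <- c("tmean", "rhmean", "rs", "u2")
  rows <- lapply(vars, function(v) {
    x <- records[[v]]
    s <- stats::sd(x)
    skew <- if (length(x) >= 3 && s > 0) sample_skewness(x) else {
      warning("skewness undefined for ", v, call. = FALSE)
      NA_real_
    }
    data.frame(variable = v, mean = mean(x), sd = s, skew = skew,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
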