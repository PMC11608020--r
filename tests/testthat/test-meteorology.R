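# Vapour-pressure chain, radiation terms, conversions, skewness.

test_that("saturation vapour pressure matches the arithmetic oracle and is increasing", {
  expect_equal(saturation_vapour_pressure(0), 0.6108)
  expect_equal(saturation_vapour_pressure(20), oracle_es(20), tolerance = 1e-12)
  expect_equal(saturation_vapour_pressure(30), 4.243065, tolerance = 1e-6)
  t_grid <- seq(-20, 50, by = 0.5)
  expect_true(all(diff(saturation_vapour_pressure(t_grid)) > 0))
  expect_error(saturation_vapour_pressure(NA_real_), "finite")
  expect_error(saturation_vapour_pressure(-240), "domain")
})

test_that("mean saturation pressure averages the two extremes", {
  expect_equal(mean_saturation_vapour_pressure(20, 20),
               saturation_vapour_pressure(20))
  expect_equal(mean_saturation_vapour_pressure(30, 20),
               (oracle_es(30) + oracle_es(20)) / 2, tolerance = 1e-12)
  expect_equal(mean_saturation_vapour_pressure(0, 0), 0.6108)
  for (t in c(-5, 3.2, 17, 41)) {
    expect_equal(mean_saturation_vapour_pressure(t, t),
                 saturation_vapour_pressure(t))
  }
  expect_error(mean_saturation_vapour_pressure(10, 20), "tmin")
})

test_that("actual vapour pressure follows the humidity-weighted form", {
  es_mean <- mean_saturation_vapour_pressure(30, 20)
  expect_equal(actual_vapour_pressure(30, 20, 100, 100), es_mean)
  expect_equal(actual_vapour_pressure(30, 20, 0, 0), 0)
  expect_equal(actual_vapour_pressure(30, 20, 80, 40),
               (oracle_es(20) * 0.8 + oracle_es(30) * 0.4) / 2,
               tolerance = 1e-12)
  expect_equal(actual_vapour_pressure(30, 20, 80, 40), 1.783926,
               tolerance = 1e-6)
  expect_error(actual_vapour_pressure(30, 20, 120, 40), "\\[0, 100\\]")
})

test_that("ea never exceeds es on physically consistent records", {
  w <- random_weather(300, seed = 11)
  es <- mean_saturation_vapour_pressure(w$tmax, w$tmin)
  ea <- actual_vapour_pressure(w$tmax, w$tmin, w$rhmax, w$rhmin)
  expect_true(all(ea <= es + 1e-12))
})

test_that("VPD subtracts and flags negative deficits without clipping", {
  expect_equal(vapour_pressure_deficit(2, 2), 0)
  expect_equal(vapour_pressure_deficit(3.2906, 1.7839), 1.5067)
  expect_warning(v <- vapour_pressure_deficit(1.0, 1.2), "negative VPD")
  expect_equal(v, -0.2)
  expect_error(vapour_pressure_deficit(-1, 0), "non-negative")
})

test_that("saturation-curve slope matches the oracle and is increasing", {
  expect_equal(slope_saturation_curve(21.5),
               4098 * oracle_es(21.5) / (21.5 + 237.3)^2, tolerance = 1e-12)
  expect_equal(slope_saturation_curve(21.5), 0.1569035, tolerance = 1e-6)
  expect_equal(slope_saturation_curve(0), 4098 * 0.6108 / 237.3^2,
               tolerance = 1e-12)
  expect_gt(slope_saturation_curve(25), slope_saturation_curve(15))
})

test_that("psychrometric constant follows the pressure profile", {
  expect_equal(atmospheric_pressure(0), 101.3)
  expect_equal(psychrometric_constant(0), 0.000665 * 101.3)
  expect_equal(psychrometric_constant(1669), 0.055239, tolerance = 1e-5)
  expect_lt(psychrometric_constant(2000), psychrometric_constant(0))
})

test_that("net radiation matches the staged oracle on 100 random inputs", {
  set.seed(21)
  st <- station_meta(38.4667, 1669)
  # frozen single case computed with the staged oracle before the build
  expect_equal(
    net_radiation(24, 30, 15, 1.5, st, 196),
    14.275915, tolerance = 1e-5)
  for (i in 1:100) {
    lat <- runif(1, -60, 60)
    elev <- runif(1, 0, 3000)
    stn <- station_meta(lat, elev)
    doy <- sample(1:365, 1)
    tmin <- runif(1, -5, 20); tmax <- tmin + runif(1, 2, 18)
    ea <- runif(1, 0.3, 3)
    rs <- runif(1, 0, 30)
    expect_equal(net_radiation(rs, tmax, tmin, ea, stn, doy),
                 oracle_net_radiation(rs, tmax, tmin, ea, lat, elev, doy),
                 tolerance = 1e-9)
  }
})

test_that("net radiation edge behaviour", {
  st <- station_meta(38.4667, 1669)
  # zero shortwave: Rns vanishes, only longwave remains (here negative Rnl
  # because the rs/Rso ratio is 0)
  rn0 <- net_radiation(0, 20, 10, 1, st, 180)
  expect_equal(rn0, oracle_net_radiation(0, 20, 10, 1, 38.4667, 1669, 180),
               tolerance = 1e-12)
  expect_gt(rn0, 0)  # 0.35 * sigma * T^4 * (0.34 - 0.14 sqrt(ea)) > 0
  # monotone in rs on the study range
  rs_grid <- seq(5, 25, by = 5)
  rn <- vapply(rs_grid, function(r) net_radiation(r, 30, 15, 1.5, st, 196),
               numeric(1))
  expect_true(all(diff(rn) > 0))
  # polar night with positive rs is inconsistent
  polar <- station_meta(-80, 100)
  expect_error(net_radiation(5, -10, -20, 0.3, polar, 172), "polar night")
})

test_that("unit conversions are exact and linear", {
  expect_equal(convert_pressure(1, "hPa"), 10)
  expect_equal(convert_pressure(1, "mmHg"), 760 / 101.325)
  expect_equal(convert_pressure(1, "mmHg"), 7.500617, tolerance = 1e-6)
  expect_equal(convert_pressure(0, "hPa"), 0)
  expect_equal(convert_wind_to_miles_per_day(0), 0)
  expect_equal(convert_wind_to_miles_per_day(1), 86400 / 1609.344)
  expect_equal(convert_wind_to_miles_per_day(2.65), 142.269148,
               tolerance = 1e-6)
  a <- 1.3; b <- 2.9
  expect_equal(convert_pressure(a + b, "mmHg"),
               convert_pressure(a, "mmHg") + convert_pressure(b, "mmHg"))
  expect_equal(convert_wind_to_miles_per_day(a + b),
               convert_wind_to_miles_per_day(a) + convert_wind_to_miles_per_day(b))
  expect_error(convert_pressure(1, "psi"))
  expect_error(convert_wind_to_miles_per_day(-1), "non-negative")
})

test_that("wind profile correction is pass-through at 2 m", {
  expect_identical(adjust_wind_to_2m(3.1, 2), 3.1)
  u10 <- adjust_wind_to_2m(5, 10)
  expect_equal(u10, 5 * 4.87 / log(67.8 * 10 - 5.42))
  expect_lt(u10, 5)
})

test_that("sample skewness is spreadsheet-compatible and affine-invariant", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  expect_equal(sample_skewness(c(1, 2, 3, 4, 10)),
               oracle_skew(c(1, 2, 3, 4, 10)), tolerance = 1e-12)
  expect_equal(sample_skewness(c(1, 2, 3, 4, 10)), 1.69705627,
               tolerance = 1e-7)
  set.seed(5)
  x <- rnorm(50)
  expect_equal(sample_skewness(3 * x + 7), sample_skewness(x),
               tolerance = 1e-10)
  expect_error(sample_skewness(c(1, 2)), "at least 3")
  expect_error(sample_skewness(rep(2, 10)), "zero-variance")
})

test_that("station metadata validates its bounds", {
  st <- van_station()
  expect_equal(st$latitude, 38 + 28 / 60, tolerance = 1e-12)
  expect_equal(st$elevation, 1669)
  expect_error(station_meta(95, 100), "latitude")
  expect_error(station_meta(40, -500), "elevation")
  expect_error(station_meta(40, 100, 0), "anemometer")
})

test_that("as_weather enforces schema and drops invalid rows", {
  w <- make_weather(3)
  expect_silent(v <- as_weather(w))
  expect_equal(nrow(v), 3)
  w_bad <- w; w_bad$rhmax[2] <- 120
  expect_warning(v2 <- as_weather(w_bad), "dropped 1")
  expect_equal(nrow(v2), 2)
  expect_error(as_weather(w[-2]), "missing column")
  w_na <- w; w_na$date <- c("2020-06-01", "notadate", "2020-06-03")
  expect_error(as_weather(w_na), "unparseable")
})
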