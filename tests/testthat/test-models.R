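# ET0 estimators and the unit-dialect dispatcher.

test_that("FAO-56 PM matches the single-expression oracle", {
  expect_equal(et0_fao56_pm(0.1569, 0.0552, 15, 0, 21.5, 2.65, 2.564, 1.5),
               oracle_pm(0.1569, 0.0552, 15, 0, 21.5, 2.65, 2.564, 1.5),
               tolerance = 1e-12)
  expect_equal(et0_fao56_pm(0.1569, 0.0552, 15, 0, 21.5, 2.65, 2.564, 1.5),
               5.483884, tolerance = 1e-6)
  # both numerator terms vanish
  expect_equal(et0_fao56_pm(0.15, 0.055, 10, 10, 20, 2, 2, 2), 0)
  # strictly increasing in the vapour pressure deficit
  vpds <- seq(0, 3, by = 0.5)
  et <- vapply(vpds, function(d)
    et0_fao56_pm(0.15, 0.055, 12, 0, 20, 2, 2 + d, 2), numeric(1))
  expect_true(all(diff(et) > 0))
  expect_error(et0_fao56_pm(-0.1, 0.055, 12, 0, 20, 2, 2, 1), "positive")
})

test_that("mass-transfer models reproduce their direct arithmetic", {
  # Dalton (vpd in hPa)
  expect_equal(et0_dalton(0, 10), 3.648)
  expect_equal(et0_dalton(2.65, 10), (0.3648 + 0.07223 * 2.65) * 10)
  expect_equal(et0_dalton(2.65, 10), 5.5621, tolerance = 1e-4)
  # Rohwer (vpd in mmHg)
  expect_equal(et0_rohwer(0, 7.5), 3.30)
  expect_equal(et0_rohwer(2.65, 7.5), 5.66115, tolerance = 1e-5)
  # Penman (wind in miles/day, vpd in mmHg)
  expect_equal(et0_penman(0, 7.5), 2.625)
  expect_equal(et0_penman(142.269, 7.5), 0.35 * (1 + 0.0098 * 142.269) * 7.5)
  expect_equal(et0_penman(142.269, 7.5), 6.2849, tolerance = 1e-4)
  # Romanenko (T and RH only)
  expect_equal(et0_romanenko(20, 100), 0)
  expect_equal(et0_romanenko(-25, 40), 0)
  expect_equal(et0_romanenko(16.42, 53.98), 4.737160, tolerance = 1e-6)
  # WMO
  expect_equal(et0_wmo(0, 10), 1.298)
  expect_equal(et0_wmo(2.65, 10), 3.7731, tolerance = 1e-4)
  # Mahringer (square-root wind term)
  expect_equal(et0_mahringer(0, 10), 0)
  expect_equal(et0_mahringer(1 / 3.6, 10), 1.5072)
  expect_equal(et0_mahringer(2.65, 10), 4.655272, tolerance = 1e-6)
})

test_that("all VPD-driven models vanish at zero deficit and stay non-negative", {
  for (f in list(et0_dalton, et0_rohwer, et0_wmo, et0_mahringer)) {
    expect_equal(f(2.2, 0), 0)
  }
  expect_equal(et0_penman(100, 0), 0)
  set.seed(31)
  u <- runif(50, 0, 8); v <- runif(50, 0, 25)
  expect_true(all(et0_dalton(u, v) >= 0))
  expect_true(all(et0_mahringer(u, v) >= 0))
  expect_true(all(et0_romanenko(runif(50, -10, 30), runif(50, 0, 100)) >= 0))
  expect_error(et0_dalton(-1, 5), "non-negative")
  expect_error(et0_romanenko(20, 110), "\\[0, 100\\]")
})

test_that("the dispatcher resolves unit dialects from internal kPa / m s-1", {
  w <- as_weather(make_weather(6))
  es <- mean_saturation_vapour_pressure(w$tmax, w$tmin)
  ea <- actual_vapour_pressure(w$tmax, w$tmin, w$rhmax, w$rhmin)
  vpd <- es - ea
  # second, manual route through the dialect conversions
  expect_equal(compute_et0(w, "dalton")$et0, et0_dalton(w$u2, vpd * 10))
  expect_equal(compute_et0(w, "rohwer")$et0,
               et0_rohwer(w$u2, vpd * 760 / 101.325))
  expect_equal(compute_et0(w, "penman")$et0,
               et0_penman(w$u2 * 86400 / 1609.344, vpd * 760 / 101.325))
  expect_equal(compute_et0(w, "wmo")$et0, et0_wmo(w$u2, vpd * 10))
  expect_equal(compute_et0(w, "mahringer")$et0,
               et0_mahringer(w$u2, vpd * 10))
  expect_equal(compute_et0(w, "romanenko")$et0,
               et0_romanenko(w$tmean, w$rhmean))
})

test_that("the dispatcher computes FAO-56 PM from weather plus station", {
  w <- as_weather(make_weather(4))
  st <- van_station()
  s <- compute_et0(w, "fao56pm", station = st)
  expect_s3_class(s, "et0_series")
  expect_identical(attr(s, "variant"), "reference")
  ea <- actual_vapour_pressure(w$tmax, w$tmin, w$rhmax, w$rhmin)
  manual <- oracle_pm(
    slope_saturation_curve(w$tmean), psychrometric_constant(st$elevation),
    oracle_net_radiation(w$rs, w$tmax, w$tmin, ea, st$latitude, st$elevation,
                         as.integer(format(w$date, "%j"))),
    0, w$tmean, w$u2,
    mean_saturation_vapour_pressure(w$tmax, w$tmin), ea)
  expect_equal(s$et0, manual, tolerance = 1e-12)
  expect_error(compute_et0(w, "fao56pm"), "station")
})

test_that("the model registry is exhaustive and unknown ids fail loudly", {
  reg <- model_registry()
  expect_setequal(reg$model_id,
                  c("fao56pm", "dalton", "rohwer", "penman", "romanenko",
                    "wmo", "mahringer"))
  expect_identical(reg$vpd_unit[reg$model_id == "rohwer"], "mmHg")
  expect_identical(reg$vpd_unit[reg$model_id == "penman"], "mmHg")
  expect_identical(reg$wind_unit[reg$model_id == "penman"], "miles_day")
  expect_identical(reg$vpd_unit[reg$model_id == "romanenko"], "n/a")
  w <- make_weather(4)
  expect_error(compute_et0(w, "trabert"), "unknown model id")
  expect_error(et0_series(Sys.Date(), 1, "meyer"), "unknown model id")
})

test_that("linear calibration is affine, commutes with means, and maps the published monthly values", {
  expect_equal(apply_linear_calibration(3.7, 1, 0), 3.7)
  set.seed(7)
  x <- runif(40, 1, 9)
  expect_equal(mean(apply_linear_calibration(x, 0.6, 1.4)),
               0.6 * mean(x) + 1.4, tolerance = 1e-12)
  # published worked examples: coefficient table applied to monthly means
  expect_equal(round(apply_linear_calibration(2.14, 0.5457, 1.3459), 2), 2.51)
  expect_equal(round(apply_linear_calibration(6.75, 0.6372, 1.4336), 2), 5.73)
  expect_warning(apply_linear_calibration(c(0.1, 5), 1, -1), "negative")
  # series route keeps dates and relabels the variant
  w <- as_weather(make_weather(4))
  s <- compute_et0(w, "dalton", coefficients = list(a = 0.5457, b = 1.3459))
  expect_identical(attr(s, "variant"), "modified")
  expect_equal(s$et0, 0.5457 * compute_et0(w, "dalton")$et0 + 1.3459)
})

test_that("et0_series validates alignment and ordering", {
  d <- as.Date("2020-05-01") + 0:2
  expect_error(et0_series(d, 1:2, "dalton"), "lengths differ")
  expect_error(et0_series(d[c(1, 3, 2)], 1:3, "dalton"),
               "strictly increasing")
})
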