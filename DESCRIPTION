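Package: etcalib
Title: Mass-Transfer Reference Evapotranspiration Models with FAO-56
    Penman-Monteith Calibration
Version: 1.0.0
Authors@R:
    person("etcalib", "developers", email = "etcalib@example.org",
           role = c("aut", "cre"))
Description: Computes daily reference evapotranspiration (ET0) with the
    FAO-56 Penman-Monteith combination equation and with six empirical
    mass-transfer models (Dalton, Rohwer, Penman, Romanenko, WMO,
    Mahringer), calibrates each mass-transfer model against FAO-56 PM by
    ordinary least squares, and evaluates original and calibrated
    estimates with MAE, MAPE, RMSE, Nash-Sutcliffe efficiency and R2
    together with the categorical accuracy bands used in semi-arid
    agro-hydrology.  Includes a seeded synthetic daily-weather generator
    emulating a high-altitude April-October growing season and a
    command-line pipeline that runs the full calibrate/validate study
    from delimited weather files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
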