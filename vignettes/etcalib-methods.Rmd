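---
title: "Methods: mass-transfer ET0 models, their calibration, and the synthetic weather world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-transfer ET0 models, their calibration, and the synthetic weather world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etcalib)
```

## The model chain

Daily reference evapotranspiration (ET₀) is computed two ways and the
empirical way is regressed onto the physical one.

**Ground truth: FAO-56 Penman–Monteith.** For each day the package derives,
from the daily extremes of temperature and humidity plus radiation and wind:

- saturation pressures `es(T) = 0.6108·exp(17.27·T/(T + 237.3))` (kPa),
  daily `es = (es(Tmax) + es(Tmin))/2`;
- actual vapour pressure `ea = (es(Tmin)·RHmax + es(Tmax)·RHmin)/200`,
  pairing the humid extreme with the cool extreme;
- the curve slope `Δ = 4098·es(Tmean)/(Tmean + 237.3)²` and psychrometric
  constant `γ = 0.000665·P(z)` from the standard-atmosphere pressure at the
  station elevation `z`;
- net radiation `Rn = 0.77·Rs − Rnl`, with the net longwave term driven by
  the Stefan–Boltzmann mean of the Kelvin temperature extremes, a humidity
  correction `0.34 − 0.14·√ea`, and a cloudiness correction
  `1.35·Rs/Rso − 0.35` from the clear-sky envelope
  `Rso = (0.75 + 2·10⁻⁵·z)·Ra`, where `Ra` is the astronomical
  top-of-atmosphere radiation for (latitude, day of year).

These feed the combination equation in `et0_fao56_pm()`.

**The six mass-transfer models.** `et0_dalton()`, `et0_rohwer()`,
`et0_penman()`, `et0_romanenko()`, `et0_wmo()` and `et0_mahringer()` are the
original published forms. Their single practical trap is units: the
historical equations expect VPD in hPa (Dalton, WMO, Mahringer) or mmHg
(Rohwer, Penman) and wind in m s⁻¹ except Penman's miles day⁻¹. The package
therefore keeps **kPa and m s⁻¹ internally everywhere**; `compute_et0()`
consults the dialect declared in `model_registry()` and converts at the
model boundary. Callers never pre-convert. The same es/ea/VPD chain feeds
both FAO-56 PM and the mass-transfer models, so differences between models
are differences of model structure, not of input preprocessing.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| soil heat flux `g` | 0 | MJ m⁻² day⁻¹ | standard daily-step assumption; the source study lists G but never states a value, so 0 is assumed and exposed |
| albedo | 0.23 | – | reference grass surface |
| mile length | 1609.344 | m | the statute mile; the historical Penman wind unit never defines its mile, so it is an argument |
| anemometer height | 2 | m | heights ≠ 2 m trigger the log-profile correction `u₂ = u_z·4.87/ln(67.8·z − 5.42)` |
| `rs/Rso` cap | 1.0 | – | measured Rs can exceed the clear-sky envelope through noise; the longwave ratio is capped for robustness |

Negative VPD (data error) and negative calibrated ET₀ are **propagated with
warnings, never clipped**, so inconsistencies stay visible.

## Calibration

The modified equation of each model is `ET₀ = a·[original] + b`, with the
FAO-56 PM series as the dependent variable and the model estimate as the
regressor. The original workflow in this literature minimises the sum of
squared differences with an iterative spreadsheet solver; that objective is
exactly the ordinary-least-squares objective, so `fit_linear_calibration()`
uses the closed form — the solver's convergence tolerance becomes
irrelevant and the result is exact. Consequences that the tests assert:

- residuals are orthogonal to the regressor and sum to zero;
- refitting on the calibrated predictions returns (1, 0);
- on the calibration set, the NSE of the calibrated predictions equals the
  fit R² (both equal 1 − SSE/SST there) — which is why published
  calibration tables show matching NSE and R² for modified models.

A secondary description in the literature inverts the slope to push it
toward unity; that is documentation of the same fit, not a second mode, and
is not implemented separately. When emulating the full study,
`run_study()` calibrates on the **multi-year average** of the training
seasons (per-calendar-day mean across years, `multi_year_average()`), the
representation used in the source workflow; the fit itself accepts any
paired daily series.

## Evaluation

`evaluate()` returns MAE, MAPE, RMSE, NSE and R². R² deliberately uses the
squared-Pearson-correlation form rather than `1 − SSE/SST`, so an
uncalibrated, strongly biased model can show R² ≈ 0.9 with negative NSE —
a combination that the categorical bands then surface. Band conventions
(the published prose ranges overlap at their endpoints; these half-open
choices are fixed and no published value falls on a boundary):

- MAPE: excellent `[0, 10)`, good `[10, 20)`, reasonable `[20, 50]`,
  inaccurate above;
- NSE: good `(0.75, 1]`, satisfying `[0.36, 0.75]`, less satisfactory below;
- acceptability (strict): MAE < 0.52 mm day⁻¹, RMSE < 0.50 mm day⁻¹,
  NSE > 0.75.

A zero in the reference series makes MAPE an error, not a silent skip —
ET₀ in the modelled climate is always positive, so a zero indicates broken
input. Monthly means are equal-weight means of daily values; the seasonal
average is the equal-weight mean of the monthly means (this reproduces the
published model-column averages exactly; the published reference-column
average appears day-weighted, so the report prints both conventions).
Validation metrics over several held-out years are arithmetic means of
per-year metrics, matching the per-year column layout of published
validation tables.

## The synthetic weather world

`generate_season()` emulates an April–October season at a high-altitude
semi-arid station. Defaults are the 2012–2020 daily climatology of the Van
Edremit station (1669 m, 38.47° N): for each variable a target mean, SD,
skewness, and observed min/max.

Design, per variable:

- **Temperature** — a sinusoidal seasonal cycle (default amplitude 7 °C,
  peak day 203) plus skew-normal noise. The cycle is centred; its variance
  and third central moment are computed, and the noise variance/skewness
  are solved so the *pooled* series hits the target SD and skewness
  (variances and third central moments of independent components add).
- **Humidity** — no separate cycle: the daily humidity anomaly is
  `ρ·sd_RH·z_T` plus an independent skewed residual, with `ρ = −0.5` by
  default. This one imposed dependence (hot days are dry days) is what
  makes the VPD — and hence every mass-transfer estimate — realistic; it
  also gives humidity its summer dip through temperature's cycle. The
  residual skewness is solved from the additivity of third moments.
- **Solar radiation** — solstice-peaked cycle (amplitude 4 MJ m⁻² day⁻¹,
  peak day 186) plus skewed noise, truncated below at 0.1 and above at the
  day's clear-sky envelope `Rso`.
- **Wind** — shifted lognormal matched to (mean, SD, skew). The skew-normal
  family is bounded at |skew| < 0.9952, so the wind target (1.41) forces a
  different family; wind gets no seasonal cycle.
- **Daily extremes** — diurnal spans drawn as Normal(12, 2) °C and
  Normal(30, 5) % (truncated positive), split symmetrically around the
  daily means and clipped to [0, 100] for humidity. These defaults produce
  VPD magnitudes that keep ET₀ in the 1.3–10 mm day⁻¹ range typical of the
  modelled climate.

Numerical choices: the skew-normal shape is solved from the target skewness
by `uniroot` at tolerance 1e-10; where the cycle decomposition demands a
noise skewness outside ±0.95 it is clamped there (feasibility limit of the
family). `min`/`max` targets are plausibility checks on the configuration,
not hard clips — clipping would distort the moments being targeted.

**What the generator does *not* emulate** — and therefore what a green test
does and does not establish: day-to-day autocorrelation (every day is an
independent draw around the cycle), cross-correlations other than T–RH
(wind and radiation are independent of everything), multi-year trends or
drought sequences, and the actual Van archive. Pooled marginal statistics
of ten generated seasons match the configured targets within stochastic
tolerance (this is tested); single-season calibrations on this world yield
R² ≈ 0.8 rather than the ≈ 0.97 of a 9-year-average series, because
averaging nine real years suppresses exactly the daily noise this generator
injects. Green tests establish that the pipeline's arithmetic is right and
that calibration recovers known coefficients — not that the generator
reproduces the real archive's joint distribution.

One tolerance in the generator-fidelity test deserves a note: sample
skewness of the lognormal wind has a sampling standard deviation of ≈ 0.16
at n = 2140 (ten seasons), several times that of the light-tailed
variables, so its band is set at four standard errors (0.65) while the
others use 0.4.

## Known limitations

- Daily time steps only; no hourly formulation, no pyranometer QC, no
  gap-filling beyond drop-and-log of invalid rows.
- The bundled published coefficient table reproduces the published
  modified-model monthly means at 2 dp for most, but not all, cells when
  applied to the published (rounded) original monthly means; a few cells
  differ by 0.01–0.02 purely through input rounding. The bundled Romanenko
  coefficients are internally inconsistent in the source tables and are
  excluded from mapping checks.
- Other historical mass-transfer models (Trabert, Meyer, Albrecht, Saif)
  are out of scope.
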