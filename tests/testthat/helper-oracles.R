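# Independent oracles, coded from the printed formulas before the package
# implementation, plus small fixture builders. These deliberately do not
# call package internals for the quantities they check.

# Tetens saturation pressure (kPa)
oracle_es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

# staged net-radiation oracle: Ra -> Rso -> Rns -> Rnl, step by step
oracle_net_radiation <- function(rs, tmax, tmin, ea, lat_deg, elev, doy) {
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(dec), -1), 1))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  rso <- (0.75 + 2e-5 * elev) * ra
  rns <- (1 - 0.23) * rs
  rnl <- 4.903e-9 * (((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2) *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * pmin(rs / rso, 1) - 0.35)
  rns - rnl
}

# single-expression Penman-Monteith oracle
oracle_pm <- function(delta, gamma, rn, g, tmean, u2, es, ea) {
  (0.408 * delta * (rn - g) + gamma * (900 / (tmean + 273)) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
}

# dense grid-search SSE minimiser for actual ~ a*estimated + b; independent
# of the closed-form OLS it checks. 1-D grid refinement is robust for a
# convex objective: the grid argmin lies within one cell of the continuous
# argmin, so recentring with a two-cell half-width never loses it. The
# slope is found on the profile SSE (b minimised out by its own grid) to
# avoid drifting along the correlated a-b valley of a joint 2-D grid.
# each round shrinks the half-width by 4/(k-1) = 0.1, so 12 rounds reach
# ~1e-11 from a half-width of 10
refine_1d <- function(f, centre, half, rounds = 12, k = 41) {
  for (r in seq_len(rounds)) {
    grid <- seq(centre - half, centre + half, length.out = k)
    centre <- grid[which.min(vapply(grid, f, numeric(1)))]
    half <- 2 * (2 * half / (k - 1))
  }
  centre
}

oracle_grid_ols <- function(x, y, half_a = 5, half_b = 10) {
  sse_b <- function(a) {
    f <- function(b) sum((x - (a * y + b))^2)
    f(refine_1d(f, 0, half_b))
  }
  a_hat <- refine_1d(sse_b, 0, half_a)
  b_hat <- refine_1d(function(b) sum((x - (a_hat * y + b))^2), 0, half_b)
  c(a = a_hat, b = b_hat)
}

# brute-force adjusted Fisher-Pearson skewness
oracle_skew <- function(x) {
  n <- length(x)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / sd(x))^3)
}

# hand-built valid weather fixture
make_weather <- function(n = 5, start = "2020-06-01") {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  tmean <- 18 + seq_len(n)
  rhmean <- 55 - seq_len(n)
  data.frame(date = dates,
             tmax = tmean + 6, tmin = tmean - 6, tmean = tmean,
             rhmax = rhmean + 15, rhmin = rhmean - 15, rhmean = rhmean,
             rs = 20 + 0.1 * seq_len(n), u2 = 2 + 0.1 * seq_len(n))
}

# random physically-valid weather rows for property tests
random_weather <- function(n, seed) {
  set.seed(seed)
  tmean <- runif(n, 5, 28)
  span <- runif(n, 4, 16)
  rhmean <- runif(n, 30, 85)
  rhspan <- runif(n, 5, 25)
  data.frame(
    date = seq(as.Date("2019-04-01"), by = "day", length.out = n),
    tmax = tmean + span / 2, tmin = tmean - span / 2, tmean = tmean,
    rhmax = pmin(rhmean + rhspan / 2, 100),
    rhmin = pmax(rhmean - rhspan / 2, 0),
    rhmean = rhmean,
    rs = runif(n, 5, 28), u2 = runif(n, 0.2, 7))
}
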