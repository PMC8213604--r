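test_that("Tetens saturation vapour pressure matches its closed form", {
  expect_equal(tetens_saturation_vp(0), 6.1078)
  expect_equal(tetens_saturation_vp(237.3), 6.1078 * 10^3.75)
  e <- tetens_saturation_vp(c(0, 10, 20))
  expect_true(all(diff(e) > 0))
  expect_error(tetens_saturation_vp(-240), "pole")
})

test_that("solar geometry behaves like the standard formulas", {
  # March mid-month is near the equinox: altitude ~ 90 - latitude
  expect_equal(sun_altitude_midmonth(3, 51.1), 90 - 51.1, tolerance = 1.5)
  expect_equal(sun_altitude_midmonth(3, 0), 90, tolerance = 3)
  expect_lt(sun_altitude_midmonth(12, 51.1), sun_altitude_midmonth(6, 51.1))
  # June day length at 51.1 N from an independent sunrise-equation oracle
  doy <- 31 + 28 + 31 + 30 + 31 + 15
  dec <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  h0 <- acos(pmin(1, pmax(-1, -tan(51.1 * pi / 180) * tan(dec))))
  oracle_daylen <- 2 * h0 * 180 / pi / 15
  expect_equal(day_length_hours(6, 51.1), oracle_daylen, tolerance = 1e-10)
  expect_equal(max_monthly_sunshine(6, 51.1), 30 * oracle_daylen)
  expect_error(sun_altitude_midmonth(13), "invalid month")
})

test_that("cloudiness is the clamped sunshine complement", {
  expect_equal(cloudiness_from_sunshine(0, 6), 100)
  s0 <- max_monthly_sunshine(6, 51.1)
  expect_equal(cloudiness_from_sunshine(s0, 6), 0)
  expect_equal(cloudiness_from_sunshine(2 * s0, 6), 0)   # clamped
  expect_equal(cloudiness_from_sunshine(s0 / 4, 6), 75)
  expect_error(cloudiness_from_sunshine(-1, 6), ">= 0")
})

test_that("absorbed radiation matches its dual transcription and bounds", {
  expect_equal(absorbed_radiation_solalt(50, 0), 0)
  expect_lt(absorbed_radiation_solalt(90, 30), absorbed_radiation_solalt(10, 30))
  # independent second transcription of the same convention
  oracle <- function(n, h) {
    sh <- sin(h / 180 * pi)
    if (sh <= 0) return(0)
    0.21 * (1367 * sh * 0.7^((1 / sh)^0.678)) * (1 - 0.75 * (n / 100)^3.4)
  }
  for (n in c(0, 25, 50, 90, 100)) for (h in c(5, 15, 30, 60))
    expect_equal(absorbed_radiation_solalt(n, h), oracle(n, h),
                 tolerance = 1e-12)
  expect_error(absorbed_radiation_solalt(120, 30), "\\[0, 100\\]")
  expect_error(absorbed_radiation_solalt(50, -3), ">= 0")
})

test_that("long-wave terms follow the documented Brunt-type conventions", {
  sigma <- 5.667e-8
  lw <- longwave_terms(20, 11.7, 0)
  expect_equal(lw$Lg, 0.95 * sigma * 293.15^4)
  # La increases with cloudiness at fixed T, e
  la_n <- vapply(c(0, 40, 80, 100),
                 function(n) longwave_terms(10, 9, n)$La, numeric(1))
  expect_true(all(diff(la_n) > 0))
  # sweep: La < Lg whenever e < 16 hPa (emissivity below 0.95)
  for (t in c(-10, 0, 15, 25)) for (e in c(2, 8, 15)) for (n in c(0, 50, 99))
    expect_lt(longwave_terms(t, e, n)$La, longwave_terms(t, e, n)$Lg)
})

test_that("mean radiant temperature satisfies the exact identities", {
  sh <- 0.95; sigma <- 5.667e-8
  # quartic-root inversion: total flux of a 300 K enclosure -> 27.0 degC
  lg <- sh * sigma * 300^4
  expect_equal(mrt(0, lg, lg, irc = 1), 27, tolerance = 1e-10)
  # 0.5 + 0.5 weighting sums to one: R = 0, Lg = La at 283 K -> 10.0 degC
  l283 <- sh * sigma * 283^4
  expect_equal(mrt(0, l283, l283), 10, tolerance = 1e-10)
  # homogeneity: doubling all fluxes scales the kelvin value by 2^0.25
  t1 <- mrt(100, 350, 300) + 273
  t2 <- mrt(200, 700, 600) + 273
  expect_equal(t2 / t1, 2^0.25, tolerance = 1e-12)
  expect_error(mrt(-400, 1, 1, irc = 1), "radicand")
})

test_that("UTCI equals air temperature near the reference environment", {
  for (t in c(-10, 0, 10, 20, 30)) {
    u <- utci(t, 0.5, 0.5 * tetens_saturation_vp(t), t)
    expect_lt(abs(u - t), 2)
  }
})

test_that("UTCI wind chill is monotone in mild conditions", {
  e20 <- 0.5 * tetens_saturation_vp(20)
  u <- vapply(c(0.5, 1, 5), function(v) utci(20, v, e20, 20), numeric(1))
  expect_true(all(diff(u) < 0))
  for (t in c(10, 18, 25)) {
    e <- 0.5 * tetens_saturation_vp(t)
    uu <- vapply(c(0.5, 1, 5), function(v) utci(t, v, e, t), numeric(1))
    expect_true(all(diff(uu) <= 0))
  }
})

test_that("the two UTCI transcriptions agree over the validity box", {
  set.seed(77)
  n <- 200
  ta <- runif(n, -50, 50); v <- runif(n, 0.5, 17)
  dtr <- runif(n, -30, 70); pa <- runif(n, 0, 5)
  d <- abs(bioclimdyn:::utci_offset_table(ta, v, dtr, pa) -
             vapply(seq_len(n), function(i)
               bioclimdyn:::utci_offset_reference(ta[i], v[i], dtr[i], pa[i]),
               numeric(1)))
  expect_lt(max(d), 1e-9)
})

test_that("UTCI rejects out-of-range input naming the bound", {
  expect_error(utci(-60, 1, 5, -60), "air temperature")
  expect_error(utci(20, 0.2, 5, 20), "wind speed")
  expect_error(utci(20, 1, 5, 95), "Tmrt - T")
  expect_error(utci(20, 1, 60, 20), "vapour pressure")
})

test_that("utci_scenario clamps sub-threshold wind with a warning", {
  expect_warning(sc <- utci_scenario(0.2), "raised to 0.5")
  expect_equal(sc$wind_speed, 0.5)
  expect_identical(utci_scenario(5)$label, "5 m/s")
  expect_error(utci_scenario(20), "above")
})

test_that("utci_series chains the monthly radiation budget", {
  # a constant mild month replicated: constant UTCI
  ds <- matrix_to_dataset(matrix(rep(c(150, 50, 15), each = 24), 24, 3))
  u <- utci_series(ds, 0.5)
  expect_s3_class(u, "monthly_series")
  expect_identical(u$variable, "utci")
  expect_true(all(attr(u, "valid")))
  # same calendar month always maps to the same UTCI
  m <- series_months(u)
  expect_equal(u$values[m == 3], rep(u$values[m == 3][1], 2))
  # scenario ordering on the synthetic world
  full <- fx_dataset()
  u05 <- utci_series(full, 0.5)
  u5 <- utci_series(full, 5)
  expect_gt(mean(u05$values, na.rm = TRUE), mean(u5$values, na.rm = TRUE))
  # slow-component UTCI is smoother than full-data UTCI.  Both series share
  # a seasonal cycle injected by the solar geometry, so the filtering
  # property is assessed on the deseasonalized UTCI.
  slow <- lapply(fx_decompositions(), function(d) d$slow)
  uslow <- utci_series(slow[c("sunshine", "precipitation", "temperature")], 0.5)
  lag1 <- function(u) {
    x <- deseasonalize(u)$residual$values
    cor(x[-1], x[-length(x)])
  }
  expect_gt(lag1(uslow), lag1(trim_series(u05, 60, 60)))
})

test_that("compare_series computes MSE and density overlap", {
  a <- monthly_series(sin(1:100), 2000, 1, "utci")
  same <- compare_series(a, a)
  expect_equal(same$mse, 0)
  expect_equal(same$pdf_overlap, 1)
  b <- a; b$values <- a$values + 1
  expect_equal(compare_series(a, b)$mse, 1)
  set.seed(88)
  x <- rnorm(1e5); y <- rnorm(1e5)
  cs <- compare_series(x, y)
  expect_equal(cs$mse, 2, tolerance = 0.05)     # var of a difference of N(0,1)
  expect_error(compare_series(1:5, 1:6), "lengths differ")
})
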