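test_that("moving_average is the exact centred window mean", {
  const <- monthly_series(rep(4.2, 300), 1900, 1, "temperature")
  ma <- moving_average(const)
  expect_length(ma$values, 300 - 120)             # centred 121-point window
  expect_equal(ma$values, rep(4.2, 180), tolerance = 1e-12)
  expect_identical(ma$start_year, 1905L)          # anchor advanced 60 months
  ramp <- monthly_series(2 + 0.05 * (1:400), 1900, 1, "temperature")
  mr <- moving_average(ramp)
  expect_equal(mr$values, 2 + 0.05 * (61:340), tolerance = 1e-12)
  # 12-month seasonal tone is attenuated to the 121-point Dirichlet gain
  n <- 1560
  tone <- monthly_series(sin(2 * pi * (1:n) / 12), 1900, 1, "temperature")
  mt <- moving_average(tone)
  gain <- abs(sin(121 * pi / 12) / (121 * sin(pi / 12)))
  expect_lt(gain, 0.01)
  expect_equal(max(abs(mt$values)), gain, tolerance = 0.05 * gain)
  expect_error(moving_average(const, 121), "even")
  expect_error(moving_average(monthly_series(1:50, 1900, 1, "sunshine")),
               "not longer than the window")
})

test_that("dominant_frequency picks the largest non-DC periodogram peak", {
  n <- 1200
  t <- 1:n
  expect_equal(dominant_frequency(sin(2 * pi * t / 600)), 2 / n)
  two <- 3 * sin(2 * pi * t / 600) + sin(2 * pi * t / 60)
  expect_equal(dominant_frequency(two), 2 / n)    # dominant amplitude wins
  expect_error(dominant_frequency(rep(1, 100)), "no spectral peak")
  # noise-free benchmark slow trend peaks within one Fourier bin of 1/642
  tr <- fx_transient_slow()
  f <- dominant_frequency(tr$temperature)
  expect_lt(abs(f - 1 / 642), 1 / 1404)
})

test_that("zero-phase Butterworth has the designed gain profile", {
  const <- rep(2.5, 500)
  expect_equal(butterworth_lowpass(const), const, tolerance = 1e-9)
  amp_ratio <- function(freq, cutoff = 0.0038) {
    n <- 6000; x <- sin(2 * pi * freq * (1:n))
    y <- butterworth_lowpass(x, cutoff = cutoff)
    mid <- 2001:4000
    sd(y[mid]) / sd(x[mid])
  }
  # two passes of |H|^2 = 1/2 at the cutoff
  expect_equal(amp_ratio(0.0038), 0.5, tolerance = 0.02)
  expect_lt(amp_ratio(0.038), 1e-3)               # 10x cutoff, order-4 roll-off
  expect_error(butterworth_lowpass(const, cutoff = 0.6), "Nyquist")
})

test_that("extract_slow recovers trends and suppresses pure seasonality", {
  const <- monthly_series(rep(7, 400), 1900, 1, "temperature")
  sl <- extract_slow(const)
  expect_lt(max(abs(sl$values - 7)), 1e-6)
  expect_error(extract_slow(monthly_series(1:200, 1900, 1, "sunshine")),
               "twice the window")
  # pure seasonal input: slow component ~ the series mean everywhere
  seas <- monthly_series(rep(default_climatology("sunshine"), 40), 1900, 1,
                         "sunshine")
  ss <- extract_slow(seas)
  expect_lt(max(abs(ss$values - mean(seas$values))),
            0.01 * abs(mean(seas$values)))
})

test_that("slow recovery on the default synthetic world is >= 0.99", {
  ds <- fx_dataset()
  truth <- attr(ds, "truth")
  dec <- fx_decompositions()
  for (v in names(ds)) {
    tt <- trim_series(truth$trend[[v]], 60, 60)$values
    expect_gt(cor(dec[[v]]$slow$values, tt), 0.99)
  }
})

test_that("deseasonalize averages by calendar month exactly", {
  pat <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  rep5 <- monthly_series(rep(pat, 5), 1900, 1, "precipitation")
  ds <- deseasonalize(rep5)
  expect_equal(ds$seasonal, pat)
  expect_equal(max(abs(ds$residual$values)), 0)
  set.seed(31)
  wn <- monthly_series(rnorm(117 * 12, sd = 2), 1891, 1, "temperature")
  dw <- deseasonalize(wn)
  expect_lt(max(abs(dw$seasonal)), 3 * 2 / sqrt(117))
  m <- series_months(dw$residual)
  permonth <- vapply(1:12, function(mm) mean(dw$residual$values[m == mm]),
                     numeric(1))
  expect_lt(max(abs(permonth)), 1e-12)
  expect_error(deseasonalize(monthly_series(1:20, 1900, 1, "sunshine")),
               "two full years")
})

test_that("standardize_series is exactly invertible and idempotent", {
  s <- standardize_series(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(mean(s$series), 0)
  expect_equal(sd(s$series), 1)
  again <- standardize_series(s$series)
  expect_equal(again$series, s$series)
  expect_equal(again$mean, 0); expect_equal(again$sd, 1)
  set.seed(8); x <- rnorm(200, 5, 3)
  st <- standardize_series(x)
  expect_lt(max(abs(st$mean + st$sd * st$series - x)) / max(abs(x)), 1e-12)
  expect_error(standardize_series(rep(1, 10)), "zero-variance")
})

test_that("decompose_series reconstructs exactly and flags degeneracy", {
  dec <- fx_decompositions()
  ds <- fx_dataset()
  for (v in names(ds)) {
    d <- dec[[v]]
    rec <- reconstruct_series(d)
    orig <- trim_series(ds[[v]], 60, 60)
    expect_lt(max(abs(rec$values - orig$values)) / max(abs(orig$values)),
              1e-10)
    expect_lt(abs(mean(d$residual_standardized$values)), 1e-10)
    expect_lt(abs(sd(d$residual_standardized$values) - 1), 1e-10)
  }
  # residual autocorrelation matches the generating AR models
  theo <- c(sunshine = 0.25, precipitation = 0.2 / (1 - 0.15), temperature = 0)
  for (v in names(ds)) {
    r1 <- correlogram(dec[[v]]$residual_standardized)$acf[2]
    expect_lt(abs(r1 - theo[[v]]), 0.05)
  }
  dconst <- decompose_series(monthly_series(rep(3, 400), 1900, 1,
                                            "temperature"))
  expect_true(dconst$degenerate)
  expect_identical(dconst$residual_sd, 0)
  expect_equal(reconstruct_series(dconst)$values, rep(3, 280),
               tolerance = 1e-9)
})

test_that("the slow extraction is linear in the input", {
  ds <- fx_dataset()
  x <- ds$sunshine; y <- ds$precipitation
  combo <- x
  combo$values <- 2 * x$values - 0.5 * y$values
  lhs <- decompose_series(combo)$slow$values
  rhs <- 2 * decompose_series(x)$slow$values -
    0.5 * decompose_series(y)$slow$values
  # machine precision amplified by the low-cutoff IIR condition number
  expect_equal(lhs, rhs, tolerance = 1e-8)
})
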