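test_that("the default climatology hits the printed monthly anchors", {
  s <- default_climatology("sunshine")
  expect_equal(s[12], 40.7)                       # December minimum
  expect_identical(which.min(s), 12L)
  expect_equal(s[8], 206)                         # August maximum
  expect_identical(which.max(s), 8L)
  p <- default_climatology("precipitation")
  expect_equal(p[2], 25.2); expect_identical(which.min(p), 2L)
  expect_equal(p[7], 89.9); expect_identical(which.max(p), 7L)
  expect_equal(sum(p), 565.6)                     # printed annual sum
  t <- default_climatology("temperature")
  expect_equal(t[1], -0.1); expect_equal(t[7], 19.7)
  expect_equal(mean(t), 9.6)                      # printed annual mean
  expect_error(default_climatology("wind"), "unknown variable")
  # profile + benchmark offset reproduces the climatology
  expect_equal(default_seasonal_profile("sunshine") + 125, s)
  expect_error(default_seasonal_profile("wind"), "unknown variable")
})

test_that("generate_slow_trend samples the benchmark ODE per the span", {
  tr <- generate_slow_trend(synthetic_config(span = c(1891, 2007)))
  expect_length(tr$sunshine$values, 1404)         # 117 years of months
  expect_identical(tr$temperature$variable, "temperature")
  # on-cycle start: temperature oscillates with the designed period
  per <- estimate_period(tr$temperature$values - mean(tr$temperature$values))
  expect_lt(abs(per$period_months - 642), 0.02 * 642)
  # zero-dynamics trend model stays at the supplied fixed point
  zm <- make_model()
  tz <- generate_slow_trend(synthetic_config(
    span = c(1900, 1910), trend_model = zm,
    trend_initial_state = c(125, 50, 8.8)))
  expect_equal(unique(tz$sunshine$values), 125)
  expect_equal(unique(tz$temperature$values), 8.8)
  # divergent custom model fails naming the offending month
  grow <- make_model(dx = c(x = 1))
  expect_error(generate_slow_trend(synthetic_config(
    span = c(1900, 1950), trend_model = grow,
    trend_initial_state = c(125, 50, 8.8), divergence_bound = 1e4)),
    "diverged at month")
})

test_that("generate_ar_noise matches AR theory and enforces stationarity", {
  n <- 1e5
  w <- generate_ar_noise(ar_model(numeric(0)), n, seed = 11)
  r1 <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(r1(w)), 3 / sqrt(n))
  a1 <- generate_ar_noise(ar_model(0.6), n, seed = 12)
  expect_lt(abs(r1(a1) - 0.6), 0.01)
  a2 <- generate_ar_noise(ar_model(c(0.3, 0.2)), n, seed = 13)
  expect_lt(abs(r1(a2) - 0.3 / (1 - 0.2)), 0.01)  # Yule-Walker closed form
  expect_error(generate_ar_noise(ar_model(c(0.9, 0.3)), 10, 1),
               "not stationary")
})

test_that("generate_dataset is additive, deterministic and well scaled", {
  cfg <- synthetic_config(seed = 5)
  ds <- generate_dataset(cfg)
  truth <- attr(ds, "truth")
  months <- series_months(ds$sunshine)
  for (v in names(ds)) {
    rebuilt <- truth$trend[[v]]$values + truth$seasonal[[v]][months] +
      truth$noise[[v]]
    expect_identical(rebuilt, ds[[v]]$values)     # machine-exact additivity
  }
  expect_identical(generate_dataset(cfg), ds)     # byte-identical re-run
  expect_true(min(ds$sunshine$values) >= 0)
  expect_true(min(ds$precipitation$values) >= 0)
  # zero seasonal + (near) zero noise reduces to the slow trend
  flat <- synthetic_config(seed = 5,
    seasonal_profiles = list(sunshine = rep(0, 12),
                             precipitation = rep(0, 12),
                             temperature = rep(0, 12)),
    noise_sd = c(sunshine = 0, precipitation = 0, temperature = 0))
  ds0 <- generate_dataset(flat)
  tr <- generate_slow_trend(flat)
  expect_equal(ds0$sunshine$values, tr$sunshine$values)
})

test_that("per-month sample means reproduce the seasonal profile (CLT)", {
  ds <- fx_dataset()
  truth <- attr(ds, "truth")
  months <- series_months(ds$sunshine)
  for (v in names(ds)) {
    seas_hat <- vapply(1:12, function(m)
      mean(ds[[v]]$values[months == m] - truth$trend[[v]]$values[months == m]),
      numeric(1))
    tol <- 3 * attr(ds, "truth")$noise_sd[[v]] / sqrt(117)
    expect_lt(max(abs(seas_hat - truth$seasonal[[v]])), tol + 1e-12)
  }
})

test_that("benchmark ensemble explores phase space as bounded segments", {
  ens <- fx_ensemble_monthly()
  expect_s3_class(ens, "slow_segments")
  X <- bioclimdyn:::slow_data_matrix(ens)
  expect_identical(sum(attr(X, "seg")), nrow(X))
  expect_identical(length(attr(X, "seg")), 16L)
  expect_true(all(is.finite(X)))
  # segments genuinely leave the limit cycle: the Hopf quadric is nonzero
  u <- (X[, 1] - 125) / 15; v <- (X[, 2] - 50) / 5
  expect_gt(max(abs(u^2 + v^2 - 0.01)), 0.05)
})
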