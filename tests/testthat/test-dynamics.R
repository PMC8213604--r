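test_that("find_equilibria locates and deduplicates real roots", {
  lin <- make_model(dx = c(x = -1), dy = c(y = -1), dz = c(z = -1))
  box <- list(lo = c(-2, -2, -2), hi = c(2, 2, 2))
  pts <- find_equilibria(lin, box, grid_n = 5)
  expect_identical(nrow(pts), 1L)
  expect_equal(unname(pts[1, ]), c(0, 0, 0), tolerance = 1e-8)
  # factored cubic: (x-1)(x-2)(x-3) = -6 + 11x - 6x^2 + x^3
  fac <- make_model(dx = c("1" = -6, x = 11, x2 = -6, x3 = 1),
                    dy = c(y = -1), dz = c(z = -1))
  pts3 <- find_equilibria(fac, list(lo = c(0, -1, -1), hi = c(4, 1, 1)),
                          grid_n = 9)
  expect_identical(nrow(pts3), 3L)
  expect_equal(unname(pts3[, 1]), c(1, 2, 3), tolerance = 1e-6)
  expect_lt(max(abs(pts3[, 2:3])), 1e-6)
  # benchmark: the single mapped fixed point, found to scaled tolerance
  box_b <- list(lo = c(118, 46, 8.5), hi = c(132, 54, 9.1))
  eq <- equilibrium_analysis(fx_benchmark(), box_b)
  expect_length(eq, 1L)
  expect_equal(unname(eq[[1]]$state), c(125, 50, 8.8), tolerance = 1e-6)
  expect_lt(eq[[1]]$residual_norm, 1e-8)
  # a 2x finer lattice adds no new roots
  pts_fine <- find_equilibria(fx_benchmark(), box_b, grid_n = 30)
  expect_identical(nrow(pts_fine), 1L)
})

test_that("benchmark eigenvalues match the Hopf closed form", {
  eq <- equilibrium_analysis(fx_benchmark(),
                             list(lo = c(118, 46, 8.5), hi = c(132, 54, 9.1)))[[1]]
  ev <- eq$eigenvalues[order(Re(eq$eigenvalues), Im(eq$eigenvalues))]
  expect_equal(ev, c(-0.02 + 0i, 0.01 - 2i * pi / 642, 0.01 + 2i * pi / 642),
               tolerance = 1e-8)
  expect_identical(eq$classification$planar, "unstable_focus")
  expect_identical(eq$classification$axial, "stable_node")
})

test_that("classify reproduces the four printed equilibrium characteristics", {
  # the published equilibrium table's eigenvalue triples and labels
  cases <- list(
    list(ev = c(0.0164 + 0.0133i, 0.0164 - 0.0133i, -0.0163),
         label = "unstable focus in (X,Y), stable node along Z"),
    list(ev = c(0.00044 + 0.0133i, 0.00044 - 0.0133i, 0.0069),
         label = "unstable focus in (X,Y), unstable node along Z"),
    list(ev = c(-0.0115 + 0.0206i, -0.0115 - 0.0206i, 0.0224),
         label = "stable focus in (X,Y), unstable node along Z"),
    list(ev = c(0.001821 + 0.00776i, 0.00182 - 0.00776i, -0.00541),
         label = "unstable focus in (X,Y), stable node along Z"))
  for (cs in cases) {
    cl <- classify_equilibrium(cs$ev)
    expect_identical(cl$label, cs$label)
    expect_true(cl$hyperbolic)
    expect_true(cl$any_unstable)     # every point unstable along >= 1 direction
  }
})

test_that("classify handles real spectra and input validation", {
  cl <- classify_equilibrium(c(-1, -2, -3))
  expect_identical(cl$planar, "stable_node")
  expect_true(cl$hyperbolic)
  expect_false(cl$any_unstable)
  expect_identical(classify_equilibrium(c(1, 2, 3))$planar, "unstable_node")
  expect_identical(classify_equilibrium(c(-1, 2, -3))$planar, "saddle")
  expect_error(classify_equilibrium(c(1, 2)), "exactly 3")
  # purity: invariant under positive scaling of all eigenvalues
  ev <- c(0.0164 + 0.0133i, 0.0164 - 0.0133i, -0.0163)
  for (s in c(0.01, 1, 250)) {
    cl2 <- classify_equilibrium(ev * s)
    expect_identical(cl2$planar, "unstable_focus")
    expect_identical(cl2$axial, "stable_node")
  }
})

test_that("long_term reports the simulated span and guards blow-ups", {
  run <- long_term(fx_benchmark(), benchmark_initial_state("cycle", "climate"),
                   steps = 7000, dt = 1)
  expect_identical(run$years, 583L)                # floor(7000/12)
  expect_true(run$completed)
  expect_identical(run$transient_cut, 2100L)
  zr <- long_term(make_model(), c(1, 1, 1), steps = 120)
  expect_identical(zr$years, 10L)
  expect_true(all(zr$trajectory[, 1] == 1))
  dv <- long_term(make_model(dx = c(x = 2)), c(10, 0, 0), steps = 500,
                  bound = 1e6)
  expect_false(dv$completed)
})

test_that("estimate_period finds the benchmark cycle and refuses flat runs", {
  x <- sin(2 * pi * (1:7000) / 642)
  p <- estimate_period(x)
  expect_lt(abs(p$period_months - 642), 1)
  run <- long_term(fx_benchmark(), benchmark_initial_state("cycle", "climate"),
                   steps = 7000)
  pb <- estimate_period(run)
  expect_lt(abs(pb$period_months - 642), 0.02 * 642)
  # independent oracle: first autocorrelation peak of the same signal
  sig <- run$trajectory[(run$transient_cut + 1):7001, 3]
  sig <- sig - mean(sig)
  ac <- stats::acf(sig, lag.max = 1000, plot = FALSE)$acf[, 1, 1]
  k <- 2:999
  peak <- k[which(ac[k] > ac[k - 1] & ac[k] > ac[k + 1] & ac[k] > 0.5)][1]
  expect_lt(abs(pb$period_months - peak) / peak, 0.02)
  flat <- long_term(make_model(), c(1, 1, 1), steps = 100)
  pf <- estimate_period(flat)
  expect_true(is.na(pf$period_months))
  expect_identical(pf$reason, "flat signal")
})

test_that("off-cycle benchmark starts are attracted to the limit cycle", {
  s0 <- c(125 + 15 * 0.02, 50, 8.8)              # interior start, r = 0.02
  run <- long_term(fx_benchmark(), s0, steps = 7000)
  late <- run$trajectory[6000:7001, ]
  r <- sqrt(((late[, 1] - 125) / 15)^2 + ((late[, 2] - 50) / 5)^2)
  expect_lt(max(abs(r - 0.1)), 0.001)            # Hopf radius sqrt(lambda)
})

test_that("the equilibrium table exports in the published layout", {
  eq <- equilibrium_analysis(fx_benchmark(),
                             list(lo = c(118, 46, 8.5), hi = c(132, 54, 9.1)))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_equilibria_csv(eq, path)
  expect_true(file.exists(path))
  expect_identical(df$point, "P1")
  expect_identical(df$characteristic,
                   "unstable focus in (X,Y), stable node along Z")
  expect_true(df$hyperbolic)
})
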