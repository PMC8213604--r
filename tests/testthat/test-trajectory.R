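# dense noise-free ensemble for the initializer recovery example
fx_ensemble_dense <- function() fx("ensemble_dense", function() {
  benchmark_ensemble(n_segments = 16L, months = 120, dt = 0.1, seed = 2,
                     substeps = 4L)
})

test_that("the quality scheme uses doubling horizons and d-spaced starts", {
  cfg <- tm_config(j_max = 10, d = 3, l_max = 4, dt = 1)
  expect_equal(bioclimdyn:::tm_horizons(cfg), c(1, 2, 4, 8))
  expect_identical(ncol(fx_benchmark()$coefficients), 20L)  # choose(6,3)
  X <- matrix(rnorm(150 * 3), 150, 3)
  expect_error(quality(make_model(), X, tm_config(j_max = 100, d = 7)),
               "infeasible")
})

test_that("quality of the exact generator is integration error only", {
  slow <- fx_transient_slow()
  q <- quality(fx_benchmark(), slow, tm_config())
  expect_true(q$stable)
  expect_lt(q$total, 1e-6)
  expect_true(all(q$Q >= 0))
})

test_that("quality of the zero-dynamics model equals the data-shift oracle", {
  X <- bioclimdyn:::slow_data_matrix(fx_transient_slow())[1:150, ]
  cfg <- tm_config(j_max = 21, d = 7, l_max = 4)  # exactly the available grid
  q <- quality(make_model(), X, cfg)
  # independent oracle: constant trajectories stay at the initial sample
  idx <- seq(1, 150 - 8, by = 7)
  expect_length(idx, 21)
  oracle <- numeric(3)
  for (h in c(1, 2, 4, 8))
    oracle <- oracle + colSums(abs(X[idx + h, , drop = FALSE] -
                                     X[idx, , drop = FALSE]))
  expect_equal(q$Q, oracle, tolerance = 1e-12)
})

test_that("perturbing an active coefficient strictly increases quality", {
  slow <- fx_transient_slow()
  cfg <- tm_config()
  q0 <- quality(fx_benchmark(), slow, cfg)$total
  m <- fx_benchmark()
  k <- which(abs(m$coefficients[1, ]) > 1e-8)[2]
  m$coefficients[1, k] <- m$coefficients[1, k] * 1.1
  expect_gt(quality(m, slow, cfg)$total, q0)
})

test_that("divergent candidates receive the finite penalty", {
  X <- bioclimdyn:::slow_data_matrix(fx_transient_slow())
  grow <- make_model(dx = c(x = 2), dy = c(y = 2), dz = c(z = 2))
  cfg <- tm_config()
  q <- quality(grow, X, cfg)
  expect_false(q$stable)
  expect_equal(q$total, 3 * cfg$penalty_unit * cfg$j_max * cfg$l_max)
})

test_that("integrate_ode matches closed forms and reports divergence", {
  zm <- make_model()
  tr <- integrate_ode(zm, c(1, 2, 3), horizon_months = 5)
  expect_true(tr$completed)
  expect_equal(tr$states[6, ], c(1, 2, 3))
  dec <- make_model(dx = c(x = -1))
  tr2 <- integrate_ode(dec, c(1, 0, 0), horizon_months = 10, dt = 1,
                       substeps = 8)
  expect_lt(abs(tr2$states[11, 1] - exp(-10)), 1e-6)
  # two full benchmark periods return to the start
  s0 <- benchmark_initial_state("cycle", "climate")
  tr3 <- integrate_ode(fx_benchmark(), s0, horizon_months = 1284, dt = 1,
                       substeps = 4)
  diam <- c(2 * 0.1 * 15, 2 * 0.1 * 5, diff(range(tr3$states[, 3])))
  expect_lt(max(abs(tr3$states[1285, ] - s0) / diam), 0.01)
  # blow-up is a structured result, not an exception
  grow <- make_model(dx = c(x = 2))
  tr4 <- integrate_ode(grow, c(10, 0, 0), horizon_months = 100, bound = 1e6)
  expect_false(tr4$completed)
  expect_lt(tr4$n_done, 100)
})

test_that("init_coefficients matches a brute-force normal-equations oracle", {
  ens <- fx_ensemble_monthly()
  X <- bioclimdyn:::slow_data_matrix(ens)
  ridge <- 1e-8
  m <- init_coefficients(ens, ridge_weight = ridge, dt = 1)
  # independent oracle: re-derive the scaled regression from scratch
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  ctr <- (hi + lo) / 2; half <- (hi - lo) / 2
  U <- sweep(sweep(X, 2, ctr), 2, half, "/")
  segs <- attr(X, "seg")
  idx <- integer(0); off <- 0
  for (len in segs) { idx <- c(idx, off + 2:(len - 1)); off <- off + len }
  ex <- cubic_exponents()
  B <- sapply(seq_len(20), function(k)
    U[idx, 1]^ex[k, 1] * U[idx, 2]^ex[k, 2] * U[idx, 3]^ex[k, 3])
  D <- (U[idx + 1, ] - U[idx - 1, ]) / 2
  oracle <- t(sapply(1:3, function(eq)
    solve(t(B) %*% B + ridge * diag(20), t(B) %*% D[, eq])[, 1]))
  got <- scaled_coefs(m, X)
  expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 1e-8)
})

test_that("the initializer recovers the benchmark from dense samples", {
  ens <- fx_ensemble_dense()
  X <- bioclimdyn:::slow_data_matrix(ens)
  m <- init_coefficients(ens, ridge_weight = 1e-8, dt = 0.1)
  ct <- scaled_coefs(fx_benchmark(), X)
  cm <- scaled_coefs(m, X)
  act <- abs(ct) > 1e-6
  expect_lt(max(abs((cm[act] - ct[act]) / ct[act])), 0.01)
  expect_lt(max(abs(cm[!act])), 1e-4)
})

test_that("initializer handles degenerate and ridgeless inputs", {
  const <- matrix(rep(c(125, 50, 8.8), each = 60), 60, 3)
  m <- init_coefficients(const, ridge_weight = 1e-6)
  expect_lt(max(abs(m$coefficients)), 1e-6)
  expect_error(init_coefficients(const, ridge_weight = 0), "ridge")
  expect_error(init_coefficients(const[1:10, ]), "at least 40")
})

test_that("a monthly-data init reproduces the short-run trajectory", {
  slow <- fx_transient_slow()
  X <- bioclimdyn:::slow_data_matrix(slow)
  m <- init_coefficients(slow, ridge_weight = 1e-8)
  tr <- integrate_ode(m, X[1, ], horizon_months = 60, dt = 1)
  expect_true(tr$completed)
  for (i in 1:3) expect_gt(cor(tr$states[, i], X[1:61, i]), 0.99)
})

test_that("refine is a monotone fixed-point iteration on quality", {
  ens <- fx_ensemble_monthly()
  cfg <- tm_config(max_iter = 5L)
  # fixed point: starting from the exact generator changes nothing material
  r0 <- refine(fx_benchmark(), ens, cfg)
  q_true <- quality(fx_benchmark(), ens, cfg)$total
  expect_lte(r0$report$total, q_true)
  # perturbed start converges most of the way back
  m <- fx_benchmark()
  act <- abs(m$coefficients) > 1e-8
  m$coefficients[act] <- m$coefficients[act] * 1.05
  q_start <- quality(m, ens, cfg)$total
  r1 <- refine(m, ens, tm_config(max_iter = 25L))
  expect_lte(r1$report$total, 0.1 * q_start)
  # generic monotonicity from a least-squares init
  m0 <- init_coefficients(ens, 1e-8)
  r2 <- refine(m0, ens, tm_config(max_iter = 8L))
  expect_lte(r2$report$total, quality(m0, ens, tm_config())$total)
})

test_that("is_stable screens bounded versus escaping dynamics", {
  slow <- fx_transient_slow()
  expect_true(is_stable(fx_benchmark(), slow))
  expect_false(is_stable(make_model(dx = c(x = 1)), slow))
  expect_true(is_stable(make_model(), slow))
})

test_that("search survives white-noise input and logs every trial", {
  set.seed(99)
  X <- matrix(rnorm(300 * 3), 300, 3)
  grid <- list(tm_config(j_max = 16, d = 7, ridge = 1e-4, max_iter = 3L),
               tm_config(j_max = 16, d = 7, ridge = 1e-2, max_iter = 0L))
  sr <- tm_search(X, grid)
  expect_identical(nrow(sr$log), 2L)
  expect_true(all(c("init_Q", "final_Q", "stable") %in% names(sr$log)))
  for (cand in sr$candidates) {
    expect_s3_class(cand$model, "poly_ode_model")
    expect_true(is_stable(cand$model, X))
  }
})
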