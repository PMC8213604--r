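# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Default synthetic dataset (the generator's stated world), seed 7.
fx_dataset <- function() fx("dataset", function() {
  generate_dataset(synthetic_config(seed = 7))
})

fx_decompositions <- function() fx("decompositions", function() {
  lapply(fx_dataset(), decompose_series)
})

# Noise-free monthly benchmark samples from a transient start (single
# trajectory; used for quality self-consistency and search examples).
fx_transient_slow <- function() fx("transient_slow", function() {
  generate_slow_trend(synthetic_config(
    trend_initial_state = benchmark_initial_state("transient")))
})

# Small noise-free monthly benchmark ensemble (coefficient recovery).
fx_ensemble_monthly <- function() fx("ensemble_monthly", function() {
  benchmark_ensemble(n_segments = 16L, months = 120, dt = 1, seed = 2)
})

# The true benchmark model in climate units and its scaled coefficients
# relative to a data matrix.
fx_benchmark <- function() fx("benchmark", function() benchmark_model("climate"))

scaled_coefs <- function(model, X) {
  sc <- bioclimdyn:::tm_scaling(X)
  bioclimdyn:::scale_model_down(model, sc$center, sc$half)$coefficients
}

# A poly_ode_model from a named coefficient assignment, e.g.
# make_model(dx = c(x = -1), dy = c(y = -1), dz = c(z = -1))
make_model <- function(dx = NULL, dy = NULL, dz = NULL) {
  co <- matrix(0, 3, 20)
  colnames(co) <- rownames(cubic_exponents())
  rows <- list(dx, dy, dz)
  for (i in 1:3)
    if (!is.null(rows[[i]])) co[i, names(rows[[i]])] <- rows[[i]]
  poly_ode_model(co)
}

# Aligned monthly dataset from a 3-column matrix.
matrix_to_dataset <- function(X, start_year = 1891) {
  list(sunshine = monthly_series(X[, 1], start_year, 1, "sunshine"),
       precipitation = monthly_series(X[, 2], start_year, 1, "precipitation"),
       temperature = monthly_series(X[, 3], start_year, 1, "temperature"))
}
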