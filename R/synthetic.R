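#' Benchmark generating system: Hopf normal form with a slaved third variable
#'
#' The fixed benchmark used throughout the package for recovery tests:
#' \deqn{\dot u = \lambda u - \omega v - u(u^2+v^2),\quad
#'       \dot v = \omega u + \lambda v - v(u^2+v^2),\quad
#'       \dot z = -\kappa (z - a u),}
#' with \eqn{\lambda = 0.01}, \eqn{\omega = 2\pi/642}, \eqn{\kappa = 0.02}
#' (all per month) and \eqn{a = 0.5}.  It has a stable limit cycle of radius
#' \eqn{\sqrt\lambda = 0.1} and period exactly 642 months (the phase velocity
#' of the normal form is \eqn{\omega} everywhere), and is exactly expressible
#' in the complete-cubic basis, also after the affine map to climate units
#' `x = 125 + 15u` (h/month), `y = 50 + 5v` (mm/month), `T = 8.8 + 0.3z`
#' (degC), so the trajectory method can in principle recover it exactly.
#'
#' @param units `"climate"` for the affinely mapped system in physical units,
#'   `"normal"` for the normal-form coordinates (u, v, z).
#' @return A [poly_ode_model()].
#' @export
benchmark_model <- function(units = c("climate", "normal")) {
  units <- match.arg(units)
  p <- benchmark_constants()
  co <- matrix(0, 3, 20)
  nm <- rownames(cubic_exponents())
  colnames(co) <- nm
  co[1, c("x", "y", "x3", "xy2")] <- c(p$lambda, -p$omega, -1, -1)
  co[2, c("x", "y", "x2y", "y3")] <- c(p$omega, p$lambda, -1, -1)
  co[3, c("x", "z")] <- c(p$kappa * p$a, -p$kappa)
  m <- poly_ode_model(co, state_units = rep("normal", 3))
  if (units == "normal") return(m)
  scale_model_up(m, center = p$center, half = p$half)
}

benchmark_constants <- function() {
  list(lambda = 0.01, omega = 2 * pi / 642, kappa = 0.02, a = 0.5,
       center = c(125, 50, 8.8), half = c(15, 5, 0.3))
}

#' Reference initial states for the benchmark system
#'
#' `"cycle"` starts exactly on the limit cycle (the slaved variable at its
#' periodic-orbit value, computed from the closed-form response of the linear
#' z-equation to the circular forcing).  `"transient"` starts off the cycle
#' so that a trajectory explores a 3-D region, which is what coefficient
#' recovery needs: on the cycle itself the quadric `u^2+v^2-\lambda` vanishes
#' identically and the cubic vector field is not identifiable.
#'
#' @param kind `"cycle"` or `"transient"`.
#' @param units `"normal"` or `"climate"`.
#' @return Length-3 numeric state.
#' @export
benchmark_initial_state <- function(kind = c("cycle", "transient"),
                                    units = c("normal", "climate")) {
  kind <- match.arg(kind); units <- match.arg(units)
  p <- benchmark_constants()
  if (kind == "cycle") {
    r <- sqrt(p$lambda)
    z0 <- p$a * r * p$kappa^2 / (p$kappa^2 + p$omega^2)
    s <- c(r, 0, z0)
  } else {
    s <- c(0.2, 0, 0.15)
  }
  if (units == "climate") p$center + p$half * s else s
}

#' Ensemble of noise-free benchmark trajectory segments
#'
#' Short trajectories of the benchmark system started from states scattered
#' uniformly in a normal-coordinate box, sampled every `dt` months and
#' mapped to climate units.  Used by the coefficient-recovery experiments:
#' unlike a single near-cycle trajectory, an ensemble explores a 3-D volume
#' of the phase space and makes the cubic vector field identifiable.
#'
#' @param n_segments Number of trajectory segments.
#' @param months Length of each segment in months.
#' @param dt Sampling interval in months.
#' @param seed Integer seed for the scattered initial states.
#' @param box Half-width of the uniform sampling box in normal coordinates.
#' @param substeps RK4 substeps per sample.
#' @return A [slow_segments()] object in climate units.
#' @export
benchmark_ensemble <- function(n_segments = 16L, months = 120, dt = 1,
                               seed = 1L, box = 0.35, substeps = 20L) {
  p <- benchmark_constants()
  m <- benchmark_model("normal")
  set.seed(as.integer(seed))
  starts <- matrix(stats::runif(3L * n_segments, -box, box), n_segments, 3L)
  segs <- lapply(seq_len(n_segments), function(i) {
    tr <- rk4_trajectory(m, starts[i, ], n_steps = round(months / dt),
                         dt = dt, substeps = substeps, bound = 1e3)
    if (!tr$completed) stop("benchmark ensemble segment diverged")
    sweep(sweep(tr$states, 2, p$half, "*"), 2, p$center, "+")
  })
  slow_segments(segs)
}

#' Printed long-term monthly climatology used as the default seasonal anchor
#'
#' Twelve monthly values per variable (January first) anchored to the
#' published Wroclaw 1966--2019 normals: sunshine minimum 40.7 h in December
#' and maximum 206 h in August (annual sum ~1490.6 h); precipitation from
#' 25.2 mm in February to 89.9 mm in July (annual sum 565.6 mm); temperature
#' from -0.1 degC in January to 19.7 degC in July (annual mean 9.6 degC).
#' Values between the printed anchors are a smooth plausible interpolation.
#'
#' @param variable `"sunshine"`, `"precipitation"` or `"temperature"`.
#' @return Numeric vector of 12 monthly values.
#' @export
default_climatology <- function(variable) {
  switch(variable,
    sunshine = c(45, 68, 112, 160, 190, 198, 198, 206, 135, 92, 47, 40.7),
    precipitation = c(28, 25.2, 33, 38, 55, 70, 89.9, 70, 45, 35, 38.5, 38),
    temperature = c(-0.1, 0.9, 4.4, 9.2, 14.3, 17.5, 19.7, 19.1, 14.7,
                    9.6, 4.7, 1.2),
    stop("unknown variable: ", variable))
}

#' Default seasonal profile (anomaly about the benchmark trend offset)
#'
#' The synthetic generator adds this profile to the slow trend, whose
#' benchmark oscillates about the offsets (125 h, 50 mm, 8.8 degC); the
#' profile is therefore the climatology of [default_climatology()] minus the
#' offset, so that trend + profile reproduces the printed monthly extremes.
#'
#' @inheritParams default_climatology
#' @return Numeric vector of 12 monthly anomalies.
#' @export
default_seasonal_profile <- function(variable) {
  off <- c(sunshine = 125, precipitation = 50, temperature = 8.8)
  if (!variable %in% names(off)) stop("unknown variable: ", variable)
  default_climatology(variable) - off[[variable]]
}

#' Configuration of the synthetic monthly dataset generator
#'
#' @param span Inclusive `(first year, last year)`; default the 117-year
#'   window 1891--2007.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @param trend_model `"benchmark"` or a [poly_ode_model()] in climate units.
#' @param trend_initial_state Initial state; `NULL` uses the benchmark
#'   on-cycle state (normal units for the benchmark, climate units for a
#'   user model).
#' @param seasonal_profiles Named list of 12-value profiles added per
#'   calendar month; default [default_seasonal_profile()] per variable.
#' @param ar_models Named list of [ar_model()] per variable; defaults mirror
#'   the orders found on the real residuals: AR(1) for sunshine, AR(2) for
#'   precipitation, white noise for temperature.
#' @param noise_sd Marginal standard deviation of the correlated noise per
#'   variable, in physical units.
#' @param seasonal_sd_profiles Optional named list of 12 positive values
#'   modulating the noise sd by calendar month (variance seasonality);
#'   `NULL` (default) means no modulation.
#' @param wind_speed Constant wind speed (m/s) recorded with the dataset.
#' @param substeps Integration substeps per month for the slow trend.
#' @param divergence_bound Abort integration when any |state| exceeds this
#'   bound (in the units the trend model is integrated in).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(span = c(1891, 2007), seed = 1L,
                             trend_model = "benchmark",
                             trend_initial_state = NULL,
                             seasonal_profiles = NULL,
                             ar_models = NULL,
                             noise_sd = c(sunshine = 1.0,
                                          precipitation = 0.35,
                                          temperature = 0.01),
                             seasonal_sd_profiles = NULL,
                             wind_speed = 0.5,
                             substeps = 20L,
                             divergence_bound = 1e6) {
  if (length(span) != 2L || span[2] < span[1])
    stop("'span' must be (first year, last year) with last >= first")
  vars <- c("sunshine", "precipitation", "temperature")
  if (is.null(seasonal_profiles))
    seasonal_profiles <- stats::setNames(lapply(vars, default_seasonal_profile), vars)
  if (is.null(ar_models))
    ar_models <- list(sunshine = ar_model(0.25),
                      precipitation = ar_model(c(0.2, 0.15)),
                      temperature = ar_model(numeric(0)))
  for (v in vars) {
    if (length(seasonal_profiles[[v]]) != 12L)
      stop("seasonal profile for ", v, " must have 12 values")
    if (!is.null(seasonal_sd_profiles) &&
        any(seasonal_sd_profiles[[v]] <= 0))
      stop("seasonal sd profile for ", v, " must be positive")
  }
  structure(list(span = as.integer(span), seed = as.integer(seed),
                 trend_model = trend_model,
                 trend_initial_state = trend_initial_state,
                 seasonal_profiles = seasonal_profiles,
                 ar_models = ar_models,
                 noise_sd = noise_sd,
                 seasonal_sd_profiles = seasonal_sd_profiles,
                 wind_speed = wind_speed,
                 substeps = as.integer(substeps),
                 divergence_bound = divergence_bound),
            class = "synthetic_config")
}

#' Generate monthly samples of the slow ODE trend
#'
#' Integrates the configured trend model (4th-order Runge-Kutta with
#' `substeps` substeps per month) over the span and returns monthly samples
#' mapped to climate units.  Deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @return Named list of three `monthly_series` (`sunshine`,
#'   `precipitation`, `temperature`).
#' @export
generate_slow_trend <- function(config) {
  n <- 12L * (config$span[2] - config$span[1] + 1L)
  bench <- identical(config$trend_model, "benchmark")
  model <- if (bench) benchmark_model("normal") else config$trend_model
  if (!inherits(model, "poly_ode_model"))
    stop("trend_model must be \"benchmark\" or a poly_ode_model")
  s0 <- config$trend_initial_state
  if (is.null(s0)) {
    if (!bench) stop("trend_initial_state required for a custom trend model")
    s0 <- benchmark_initial_state("cycle", "normal")
  }
  traj <- rk4_trajectory(model, s0, n_steps = n - 1L, dt = 1,
                         substeps = config$substeps,
                         bound = config$divergence_bound)
  if (!traj$completed) {
    month0 <- traj$n_done + 1L  # first month not reached / offending step
    stop(sprintf(
      "slow-trend integration diverged at month %d (year %d): |state| exceeded %g",
      month0, config$span[1] + (month0 - 1L) %/% 12L, config$divergence_bound))
  }
  st <- traj$states
  if (bench) {
    p <- benchmark_constants()
    st <- sweep(sweep(st, 2, p$half, "*"), 2, p$center, "+")
  }
  vars <- c("sunshine", "precipitation", "temperature")
  out <- lapply(1:3, function(i)
    monthly_series(st[, i], config$span[1], 1L, vars[i]))
  stats::setNames(out, vars)
}

#' Generate a correlated-noise realization from an AR model
#'
#' Seeded Gaussian AR(p) simulation with a burn-in of at least `10 * p`
#' samples discarded.  Shared implementation with [simulate_ar()].
#'
#' @param model An [ar_model()]; must be stationary.
#' @param n Number of samples returned.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_ar_noise <- function(model, n, seed) {
  stopifnot(inherits(model, "ar_model"))
  p <- model$order
  if (p > 0L && !ar_is_stationary(model$phi))
    stop("AR coefficients are not stationary (companion spectral radius >= 1)")
  burn <- 10L * p + 50L
  set.seed(as.integer(seed))
  eps <- stats::rnorm(n + burn, 0, sqrt(model$sigma2))
  if (p == 0L) return(model$mu + eps[burn + seq_len(n)])
  x <- numeric(n + burn)
  phi <- model$phi
  for (t in seq_len(n + burn)) {
    past <- 0
    for (j in seq_len(min(p, t - 1L))) past <- past + phi[j] * x[t - j]
    x[t] <- past + eps[t]
  }
  model$mu + x[burn + seq_len(n)]
}

#' Generate a full synthetic three-variable monthly dataset
#'
#' Each variable is `trend + seasonal(month) + noise`, where the noise is a
#' seeded AR realization standardized to unit marginal variance and scaled
#' by `noise_sd` (times the per-month sd profile when variance seasonality
#' is enabled).  The ground-truth components are attached as attribute
#' `"truth"` so recovery tests can compare against them; they sum to the
#' emitted series to machine precision.
#'
#' @param config A [synthetic_config()].
#' @return Named list of three `monthly_series` with attributes `truth`
#'   (list with `trend`, `seasonal`, `noise`, `ar_models`, `noise_sd`) and
#'   `wind_ms`.
#' @export
generate_dataset <- function(config) {
  trend <- generate_slow_trend(config)
  vars <- names(trend)
  n <- length(trend[[1]]$values)
  months <- series_months(trend[[1]])
  out <- list(); noise_l <- list()
  for (i in seq_along(vars)) {
    v <- vars[i]
    arm <- config$ar_models[[v]]
    raw <- generate_ar_noise(arm, n, seed = config$seed + 1000L * i)
    sdv <- sqrt(ar_marginal_variance(arm))
    std <- (raw - arm$mu) / sdv
    scale_m <- rep(config$noise_sd[[v]], 12L)
    if (!is.null(config$seasonal_sd_profiles))
      scale_m <- scale_m * config$seasonal_sd_profiles[[v]]
    noise <- std * scale_m[months]
    seas <- config$seasonal_profiles[[v]][months]
    vals <- trend[[v]]$values + seas + noise
    out[[v]] <- monthly_series(vals, config$span[1], 1L, trend[[v]]$variable)
    noise_l[[v]] <- noise
  }
  if (min(out$sunshine$values) < 0 || min(out$precipitation$values) < 0)
    warning("generated sunshine/precipitation contains negative values; ",
            "consider smaller noise_sd")
  attr(out, "truth") <- list(trend = trend,
                             seasonal = config$seasonal_profiles,
                             noise = noise_l,
                             ar_models = config$ar_models,
                             noise_sd = config$noise_sd)
  attr(out, "wind_ms") <- config$wind_speed
  out
}
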