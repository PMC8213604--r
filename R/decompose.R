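#' Centred moving average of a monthly series
#'
#' The ten-year "symmetric window" smoother: an even `window_months` is
#' realised as a centred window of `window_months + 1` points (the centre
#' plus `window_months/2` neighbours on each side), which keeps exact
#' symmetry and introduces no phase shift.  The output is restricted to the
#' interior months where the full window fits.
#'
#' @param series A `monthly_series`.
#' @param window_months Window width in months (even; default 120 = 10 yr).
#' @return A `monthly_series`, shortened by `window_months` points and with
#'   its calendar anchor advanced accordingly.
#' @export
moving_average <- function(series, window_months = 120L) {
  stopifnot(inherits(series, "monthly_series"))
  w <- as.integer(window_months)
  if (w %% 2L != 0L) stop("'window_months' must be even (centred window)")
  n <- length(series$values)
  if (n <= w) stop("series (", n, " months) is not longer than the window")
  k <- w %/% 2L
  cs <- cumsum(c(0, series$values))
  idx <- (k + 1L):(n - k)
  vals <- (cs[idx + k + 1L] - cs[idx - k]) / (w + 1L)
  out <- trim_series(series, head = k, tail = k)
  out$values <- vals
  out
}

#' Dominant periodogram frequency of a series
#'
#' Frequency (cycles/month) of the largest raw periodogram ordinate,
#' excluding frequency zero; no tapering; ties break toward the lower
#' frequency.
#'
#' @param series A `monthly_series` or numeric vector.
#' @return Frequency in cycles per month.
#' @export
dominant_frequency <- function(series) {
  x <- if (inherits(series, "monthly_series")) series$values else series
  x <- x - mean(x)
  if (all(x == 0)) stop("constant series: no spectral peak")
  n <- length(x)
  pg <- Mod(stats::fft(x))^2
  k <- seq_len(n %/% 2)          # positive frequencies k/n
  k[which.max(pg[k + 1L])] / n
}

# Order-n digital Butterworth low-pass (bilinear transform, fs = 1).
# Returns list(b, a) of the transfer function coefficients.
butter_design <- function(order, cutoff) {
  if (cutoff <= 0 || cutoff >= 0.5)
    stop("'cutoff' must be in (0, 0.5) cycles/month (below Nyquist)")
  wc <- 2 * tan(pi * cutoff)
  k <- seq_len(order)
  p_analog <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_digital <- (2 + p_analog) / (2 - p_analog)
  poly_from_roots <- function(r) {
    co <- 1
    for (rk in r) co <- c(co, 0) - c(0, co * rk)
    co
  }
  a <- Re(poly_from_roots(p_digital))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)   # unit DC gain
  list(b = b, a = a)
}

# Steady-state initial filter state for a unit-step input (the standard
# `lfilter_zi` construction); scaled by the first sample it removes the
# start-up transient of a near-DC-pass IIR filter, which would otherwise
# dwarf a small-amplitude slow signal.
filter_zi <- function(b, a) {
  n <- length(a)
  A <- diag(n - 1L) - cbind(-a[-1], rbind(diag(n - 2L), rep(0, n - 2L)))
  solve(A, b[-1] - a[-1] * b[1])
}

# Direct-form II transposed IIR filter (single pass) with initial state.
filter_iir <- function(b, a, x, zi = NULL) {
  n <- length(a)
  y <- numeric(length(x))
  z <- if (is.null(zi)) numeric(n - 1L) else zi
  for (t in seq_along(x)) {
    y[t] <- b[1] * x[t] + z[1]
    for (i in seq_len(n - 2L)) z[i] <- b[i + 1L] * x[t] + z[i + 1L] - a[i + 1L] * y[t]
    z[n - 1L] <- b[n] * x[t] - a[n] * y[t]
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-`order` Butterworth design (bilinear transform), applied forward
#' and backward so that no delay is introduced; the gain at the cutoff is
#' therefore the squared half-power value 0.5.  Edge transients are
#' suppressed by even (mirror) reflection padding at both ends, trimmed
#' back after filtering.
#'
#' @param series `monthly_series` or numeric vector.
#' @param cutoff Cutoff frequency in cycles/month (default 0.0038).
#' @param order Filter order (default 4).
#' @return Filtered series of the same class, length and alignment.
#' @export
butterworth_lowpass <- function(series, cutoff = 0.0038, order = 4L) {
  x <- if (inherits(series, "monthly_series")) series$values else series
  ba <- butter_design(order, cutoff)
  n <- length(x)
  pad <- min(n - 1L, ceiling(2 / cutoff))
  xp <- c(x[(pad + 1L):2], x, x[(n - 1L):(n - pad)])
  zi <- filter_zi(ba$b, ba$a)
  y <- filter_iir(ba$b, ba$a, xp, zi * xp[1])
  y <- rev(y)
  y <- rev(filter_iir(ba$b, ba$a, y, zi * y[1]))
  y <- y[pad + seq_len(n)]
  if (inherits(series, "monthly_series")) {
    out <- series; out$values <- y; out
  } else y
}

#' Extract the slow (multidecadal) component of a monthly series
#'
#' Composition of the centred moving average and the zero-phase Butterworth
#' low-pass; the result is defined on the interior months where the moving
#' average exists, with calendar alignment preserved (no artificial delay).
#'
#' @inheritParams moving_average
#' @inheritParams butterworth_lowpass
#' @return A `monthly_series` on the interior calendar window.
#' @export
extract_slow <- function(series, window_months = 120L, cutoff = 0.0038,
                         order = 4L) {
  n <- length(series$values)
  if (n < 2L * window_months)
    stop("series must be at least twice the window length")
  butterworth_lowpass(moving_average(series, window_months),
                      cutoff = cutoff, order = order)
}

#' Seasonal profile and residual of a detrended series
#'
#' The seasonal profile is the mean of the detrended values per calendar
#' month; the residual is the detrended series minus its month's profile
#' value, so per-calendar-month residual means are zero to machine
#' precision.
#'
#' @param detrended A `monthly_series` spanning at least two full years.
#' @return List with `seasonal` (12 values, January first) and `residual`
#'   (`monthly_series`).
#' @export
deseasonalize <- function(detrended) {
  stopifnot(inherits(detrended, "monthly_series"))
  m <- series_months(detrended)
  if (length(detrended$values) < 24L)
    stop("detrended series must span at least two full years")
  if (length(unique(m)) < 12L)
    stop("calendar months ", paste(setdiff(1:12, unique(m)), collapse = ","),
         " are absent from the series")
  seasonal <- vapply(1:12, function(mm) mean(detrended$values[m == mm]),
                     numeric(1))
  res <- detrended
  res$values <- detrended$values - seasonal[m]
  list(seasonal = seasonal, residual = res)
}

#' Standardize a series to zero mean and unit variance
#'
#' @param x `monthly_series` or numeric vector.
#' @return List with `series` (standardized, same class as input), `mean`
#'   and `sd`; the inverse transform `mean + sd * series` reconstructs the
#'   input exactly.
#' @export
standardize_series <- function(x) {
  v <- if (inherits(x, "monthly_series")) x$values else x
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (!is.finite(sdv) || sdv == 0)
    stop("zero-variance series cannot be standardized")
  sv <- (v - mu) / sdv
  out <- if (inherits(x, "monthly_series")) { y <- x; y$values <- sv; y } else sv
  list(series = out, mean = mu, sd = sdv)
}

#' Decompose a monthly series into slow, seasonal and standardized residual
#'
#' Chains [extract_slow()], subtraction, [deseasonalize()] and
#' [standardize_series()].  On the interior months (where the moving-average
#' window fits) the components reconstruct the input exactly:
#' `slow + seasonal[month] + residual_mean + residual_sd *
#' residual_standardized`.  A zero-variance residual (e.g. a constant input)
#' is flagged `degenerate` instead of raising, with `residual_sd = 0`.
#'
#' @inheritParams extract_slow
#' @return An object of class `decomposition` with fields `slow`,
#'   `seasonal`, `residual_standardized`, `residual_mean`, `residual_sd`,
#'   `cutoff_frequency`, `window_months`, `degenerate`.
#' @export
decompose_series <- function(series, window_months = 120L, cutoff = 0.0038,
                             order = 4L) {
  slow <- extract_slow(series, window_months, cutoff, order)
  k <- window_months %/% 2L
  interior <- trim_series(series, head = k, tail = k)
  fast <- interior
  fast$values <- interior$values - slow$values
  ds <- deseasonalize(fast)
  sdv <- stats::sd(ds$residual$values)
  # a residual at the level of filter roundoff (the IIR recursion amplifies
  # eps by its condition number) is degenerate, not signal
  degen_tol <- 1e-8 * max(1, max(abs(series$values)))
  if (!is.finite(sdv) || sdv < degen_tol) {
    std <- ds$residual; std$values <- rep(0, length(std$values))
    res <- list(series = std, mean = mean(ds$residual$values), sd = 0)
    degenerate <- TRUE
  } else {
    res <- standardize_series(ds$residual)
    degenerate <- FALSE
  }
  structure(list(slow = slow, seasonal = ds$seasonal,
                 residual_standardized = res$series,
                 residual_mean = res$mean, residual_sd = res$sd,
                 cutoff_frequency = cutoff, window_months = window_months,
                 degenerate = degenerate),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "<decomposition> %d interior months; seasonal range [%.3g, %.3g]; residual sd %.4g%s\n",
    length(x$slow$values), min(x$seasonal), max(x$seasonal), x$residual_sd,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Reconstruct the original interior series from a decomposition
#' @param d A `decomposition`.
#' @return A `monthly_series` equal to the decomposed input on the interior.
#' @export
reconstruct_series <- function(d) {
  out <- d$slow
  m <- series_months(out)
  out$values <- d$slow$values + d$seasonal[m] + d$residual_mean +
    d$residual_sd * d$residual_standardized$values
  out
}

#' Serialize a decomposition to JSON
#' @param d A `decomposition`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (or JSON string), invisibly.
#' @export
write_decomposition_json <- function(d, path = NULL) {
  obj <- list(slow = list(start_year = d$slow$start_year,
                          start_month = d$slow$start_month,
                          values = d$slow$values,
                          variable = d$slow$variable),
              seasonal = d$seasonal,
              residual_standardized = d$residual_standardized$values,
              residual_mean = d$residual_mean, residual_sd = d$residual_sd,
              cutoff_frequency = d$cutoff_frequency,
              window_months = d$window_months, degenerate = d$degenerate)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}
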