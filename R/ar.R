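#' Autoregressive model AR(p)
#'
#' The model `x_t = mu + sum_j phi_j (x_{t-j} - mu) + eps_t` with Gaussian
#' innovations `eps_t ~ N(0, sigma2)`.  `p = 0` is pure white noise.
#'
#' @param phi Numeric vector of p autoregressive coefficients (possibly
#'   empty).
#' @param mu Process mean.
#' @param sigma2 Innovation variance (> 0).
#' @return An object of class `ar_model`.
#' @export
ar_model <- function(phi = numeric(0), mu = 0, sigma2 = 1) {
  phi <- as.numeric(phi)
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  structure(list(order = length(phi), phi = phi, mu = mu, sigma2 = sigma2),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> AR(%d)", x$order))
  if (x$order > 0)
    cat(" phi =", paste(signif(x$phi, 4), collapse = ", "))
  cat(sprintf("; mu = %.4g, sigma2 = %.4g\n", x$mu, x$sigma2))
  invisible(x)
}

# Companion-matrix stationarity check: all eigenvalues inside the unit circle.
ar_is_stationary <- function(phi) {
  p <- length(phi)
  if (p == 0L) return(TRUE)
  A <- matrix(0, p, p)
  A[1, ] <- phi
  if (p > 1L) A[cbind(2:p, 1:(p - 1))] <- 1
  max(Mod(eigen(A, only.values = TRUE)$values)) < 1
}

# Theoretical autocovariances gamma_0..gamma_max_lag via the VAR(1)
# companion form and a Lyapunov solve, then the Yule-Walker recursion.
ar_autocovariances <- function(model, max_lag) {
  p <- model$order
  if (p == 0L) return(c(model$sigma2, rep(0, max_lag)))
  if (!ar_is_stationary(model$phi)) stop("AR model is not stationary")
  A <- matrix(0, p, p)
  A[1, ] <- model$phi
  if (p > 1L) A[cbind(2:p, 1:(p - 1))] <- 1
  S <- matrix(0, p, p); S[1, 1] <- model$sigma2
  G <- matrix(solve(diag(p * p) - kronecker(A, A), as.vector(S)), p, p)
  g <- numeric(max_lag + 1L)
  g[seq_len(min(p, max_lag + 1L))] <- G[1, seq_len(min(p, max_lag + 1L))]
  if (max_lag + 1L > p)
    for (k in (p + 1L):(max_lag + 1L))
      g[k] <- sum(model$phi * g[k - seq_len(p)])
  g
}

#' Theoretical autocorrelation function of an AR model
#' @param model An [ar_model()].
#' @param max_lag Largest lag.
#' @return Numeric vector `rho_0..rho_max_lag` (rho_0 = 1).
#' @export
ar_theoretical_acf <- function(model, max_lag) {
  g <- ar_autocovariances(model, max_lag)
  g / g[1]
}

#' Theoretical marginal variance of an AR model
#' @param model An [ar_model()].
#' @return The stationary variance of the process.
#' @export
ar_marginal_variance <- function(model) ar_autocovariances(model, 0L)[1]

#' Sample ACF and PACF with significance band
#'
#' Biased-normalization sample autocorrelation and partial autocorrelation
#' (Durbin-Levinson recursion on the sample ACF), with the usual
#' `+/- 1.96/sqrt(n)` white-noise band.
#'
#' @param x Numeric vector or `monthly_series`.
#' @param max_lag Largest lag (must be below half the sample size).
#' @return A list of class `correlogram` with `lags`, `acf` (including lag
#'   0), `pacf` (lags 1..max_lag), `n` and `bound`.
#' @export
correlogram <- function(x, max_lag = 20L) {
  if (inherits(x, "monthly_series")) x <- x$values
  n <- length(x)
  if (max_lag >= n / 2) stop("'max_lag' must be below half the series length")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("constant series: ACF undefined")
  rho <- vapply(0:max_lag, function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom, numeric(1))
  # Durbin-Levinson
  pacf <- numeric(max_lag)
  phi_prev <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1L) {
      phik <- rho[2]
      phi_prev <- phik
    } else {
      num <- rho[k + 1] - sum(phi_prev * rho[k:2])
      den <- 1 - sum(phi_prev * rho[2:k])
      phik <- num / den
      phi_prev <- c(phi_prev - phik * rev(phi_prev), phik)
    }
    pacf[k] <- phik
  }
  structure(list(lags = 0:max_lag, acf = rho, pacf = pacf, n = n,
                 bound = 1.96 / sqrt(n)),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> n = %d, band +/- %.4f\n", x$n, x$bound))
  k <- seq_len(min(6L, length(x$pacf)))
  cat("  acf ", paste(signif(x$acf[k + 1], 3), collapse = " "), "...\n")
  cat("  pacf", paste(signif(x$pacf[k], 3), collapse = " "), "...\n")
  invisible(x)
}

#' Select the AR order from a correlogram
#'
#' The order is the length of the initial run of PACF lags (starting at lag
#' 1) whose magnitude exceeds the significance band, capped at `cap` to
#' avoid picking up seasonal aliases.  Returns 0 when the lag-1 PACF is
#' inside the band.
#'
#' @param cg A [correlogram()].
#' @param cap Maximum order considered.
#' @return Integer order p >= 0.
#' @export
select_order <- function(cg, cap = 12L) {
  sig <- abs(cg$pacf) > cg$bound
  p <- 0L
  for (k in seq_len(min(cap, length(sig)))) {
    if (sig[k]) p <- k else break
  }
  p
}

#' Fit an AR(p) model by Yule-Walker
#'
#' Coefficients solve the Yule-Walker equations built from the biased
#' sample ACF; the mean is the sample mean and the innovation variance is
#' the variance of the fitted one-step residuals.
#'
#' @param x Numeric vector or `monthly_series`.
#' @param p Order (>= 0).
#' @return An [ar_model()].
#' @export
fit_ar <- function(x, p) {
  if (inherits(x, "monthly_series")) x <- x$values
  p <- as.integer(p)
  if (p < 0L) stop("'p' must be non-negative")
  mu <- mean(x)
  if (p == 0L)
    return(ar_model(numeric(0), mu = mu,
                    sigma2 = sum((x - mu)^2) / length(x)))
  cg <- correlogram(x, max_lag = p)
  R <- stats::toeplitz(cg$acf[seq_len(p)])
  phi <- tryCatch(solve(R, cg$acf[2:(p + 1)]),
                  error = function(e)
                    stop("Yule-Walker system is singular: ", conditionMessage(e)))
  m <- ar_model(phi, mu = mu, sigma2 = 1)
  res <- ar_residuals(m, x)
  m$sigma2 <- sum((res - mean(res))^2) / length(res)
  if (!ar_is_stationary(phi))
    stop("Yule-Walker returned a non-stationary model")  # cannot happen for PD R
  m
}

# One-step-ahead innovations of `model` on `x` (defined for t > p).
ar_residuals <- function(model, x) {
  if (inherits(x, "monthly_series")) x <- x$values
  p <- model$order
  n <- length(x)
  xc <- x - model$mu
  if (p == 0L) return(xc)
  t <- (p + 1L):n
  pred <- rep(0, length(t))
  for (j in seq_len(p)) pred <- pred + model$phi[j] * xc[t - j]
  xc[t] - pred
}

#' Whiteness check of AR fit residuals
#'
#' Computes the residual ACF at lags 1..`max_lag`, the fraction inside the
#' `+/- 1.96/sqrt(n)` band, and the Ljung-Box statistic with degrees of
#' freedom adjusted for the fitted order.  The check passes when at least
#' 93% of the residual ACF lags lie inside the band.
#'
#' @param model A fitted [ar_model()].
#' @param x The series the model was fitted to.
#' @param max_lag Number of lags examined.
#' @return List with `pass`, `frac_in_band`, `acf`, `ljung_box` (statistic,
#'   df, p_value), `n`.
#' @export
residual_whiteness <- function(model, x, max_lag = 20L) {
  res <- ar_residuals(model, x)
  cg <- correlogram(res, max_lag = max_lag)
  rho <- cg$acf[-1]
  frac <- mean(abs(rho) <= cg$bound)
  n <- cg$n
  qstat <- n * (n + 2) * sum(rho^2 / (n - seq_len(max_lag)))
  df <- max(1L, max_lag - model$order)
  list(pass = frac >= 0.93, frac_in_band = frac, acf = rho,
       ljung_box = list(statistic = qstat, df = df,
                        p_value = stats::pchisq(qstat, df, lower.tail = FALSE)),
       n = n)
}

#' Simulate from an AR model
#'
#' Same contract and implementation as [generate_ar_noise()].
#'
#' @inheritParams generate_ar_noise
#' @return Numeric vector of length `n`.
#' @export
simulate_ar <- function(model, n, seed) generate_ar_noise(model, n, seed)

#' Serialize / read an AR model as JSON
#' @param model An [ar_model()].
#' @param path File path; `NULL` returns the JSON string.
#' @return `path` (or JSON string), invisibly.
#' @export
write_ar_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(list(order = model$order, phi = model$phi,
                              mu = model$mu, sigma2 = model$sigma2),
                         digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname write_ar_json
#' @export
read_ar_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  ar_model(phi = as.numeric(o$phi), mu = o$mu, sigma2 = o$sigma2)
}
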