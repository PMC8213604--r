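#' Saturation water-vapour pressure (Tetens, over water)
#'
#' `e_sat = 6.1078 * 10^(7.5 T / (T + 237.3))` hPa.
#'
#' @param t_air Air temperature in degC (must exceed -237.3).
#' @return Saturation vapour pressure in hPa.
#' @export
tetens_saturation_vp <- function(t_air) {
  if (any(t_air <= -237.3))
    stop("temperature at or below the Tetens pole (-237.3 degC)")
  6.1078 * 10^(7.5 * t_air / (t_air + 237.3))
}

#' Solar radiation absorbed by a person, from cloudiness and sun altitude
#'
#' Sun-altitude ("SolAlt"-style) parameterization: clear-sky global
#' irradiance from the solar altitude with a Meinel air-mass transmission
#' (`1367 sin h * 0.7^((1/sin h)^0.678)` W m-2), attenuated by cloudiness
#' with the Kasten-Czeplak factor `1 - 0.75 (N/100)^3.4`, and converted to
#' radiation absorbed by a standing person with absorptivity 0.7 and
#' projected-area factor 0.3.  The exact published sub-formulas of the
#' MENEX 2005 model are not restated in accessible form; this rendering is
#' an explicit documented convention with the same interface and the same
#' qualitative structure (zero below the horizon, monotone decreasing in
#' cloudiness).
#'
#' @param n_cloud Cloudiness in percent (0..100).
#' @param h_sl Solar altitude in degrees (>= 0).
#' @return Absorbed solar radiation in W m-2.
#' @export
absorbed_radiation_solalt <- function(n_cloud, h_sl) {
  if (any(n_cloud < 0 | n_cloud > 100))
    stop("cloudiness must be within [0, 100] %")
  if (any(h_sl < 0)) stop("solar altitude must be >= 0 degrees")
  sinh_ <- sin(h_sl * pi / 180)
  kclear <- ifelse(sinh_ <= 0, 0,
                   1367 * sinh_ * 0.7^((1 / sinh_)^0.678))
  kglob <- kclear * (1 - 0.75 * (n_cloud / 100)^3.4)
  0.7 * 0.3 * kglob
}

#' Ground and atmospheric long-wave radiation terms
#'
#' Conventions for the two long-wave fluxes entering the mean radiant
#' temperature: ground radiation `Lg = 0.95 sigma (T+273.15)^4` with ground
#' temperature approximated by air temperature, and atmospheric back
#' radiation `La = eps_a sigma (T+273.15)^4` with Brunt-type clear-sky
#' emissivity `eps0 = 0.526 + 0.065 sqrt(e)` and cloud correction
#' `eps_a = eps0 (1 + 0.22 (N/100)^2)`.
#'
#' @param t_air Air temperature, degC.
#' @param e Water vapour pressure, hPa.
#' @param n_cloud Cloudiness, percent.
#' @return List with `Lg` and `La` in W m-2.
#' @export
longwave_terms <- function(t_air, e, n_cloud) {
  sigma <- 5.667e-8
  tk4 <- (t_air + 273.15)^4
  eps0 <- 0.526 + 0.065 * sqrt(pmax(e, 0))
  eps_a <- eps0 * (1 + 0.22 * (n_cloud / 100)^2)
  list(Lg = 0.95 * sigma * tk4, La = eps_a * sigma * tk4)
}

#' Mean radiant temperature from the radiation budget
#'
#' `Tmrt = ((R/Irc + 0.5 Lg + 0.5 La) / (sh * sigma))^0.25 - 273` with the
#' human emissivity `sh = 0.95` and `sigma = 5.667e-8 W m-2 K-4`.  `Irc` is
#' the coefficient reducing radiative/convective heat transfer through
#' clothing (default 1.15, a documented convention).
#'
#' @param r_abs Absorbed solar radiation, W m-2 (>= 0).
#' @param lg Ground radiation, W m-2.
#' @param la Atmospheric back radiation, W m-2.
#' @param irc Clothing heat-transfer reduction coefficient.
#' @return Mean radiant temperature in degC.
#' @export
mrt <- function(r_abs, lg, la, irc = 1.15) {
  sh <- 0.95; sigma <- 5.667e-8
  radicand <- (r_abs / irc + 0.5 * lg + 0.5 * la) / (sh * sigma)
  if (any(radicand <= 0))
    stop("non-positive radicand in the mean radiant temperature")
  radicand^0.25 - 273
}

# Exponent table of the operational UTCI polynomial: all 210 monomials
# ta^i * va^j * dtr^k * pa^l with i+j+k+l <= 6, enumerated with pa-power
# outermost, then dtr, then va, then ta (the order of the published
# coefficient listing).
utci_exponent_table <- function() {
  rows <- vector("list", 210L)
  idx <- 0L
  for (l in 0:6) for (k in 0:(6 - l)) for (j in 0:(6 - l - k))
    for (i in 0:(6 - l - k - j)) {
      idx <- idx + 1L
      rows[[idx]] <- c(i, j, k, l)
    }
  do.call(rbind, rows)
}

# The 210 published coefficients, in the same order.
utci_coefficients <- function() {
  c(0.607562052, -0.0227712343, 8.06470249e-4, -1.54271372e-4,
    -3.24651735e-6, 7.32602852e-8, 1.35959073e-9, -2.25836520,
    0.0880326035, 0.00216844454, -1.53347087e-5, -5.72983704e-7,
    -2.55090145e-9, -0.751269505, -0.00408350271, -5.21670675e-5,
    1.94544667e-6, 1.14099531e-8, 0.158137256, -6.57263143e-5,
    2.22697524e-7, -4.16117031e-8, -0.0127762753, 9.66891875e-6,
    2.52785852e-9, 4.56306672e-4, -1.74202546e-7, -5.91491269e-6,
    0.398374029, 1.83945314e-4, -1.73754510e-4, -7.60781159e-7,
    3.77830287e-8, 5.43079673e-10, -0.0200518269, 8.92859837e-4,
    3.45433048e-6, -3.77925774e-7, -1.69699377e-9, 1.69992415e-4,
    -4.99204314e-5, 2.47417178e-7, 1.07596466e-8, 8.49242932e-5,
    1.35191328e-6, -6.21531254e-9, -4.99410301e-6, -1.89489258e-8,
    8.15300114e-8, 7.55043090e-4, -5.65095215e-5, -4.52166564e-7,
    2.46688878e-8, 2.42674348e-10, 1.54547250e-4, 5.24110970e-6,
    -8.75874982e-8, -1.50743064e-9, -1.56236307e-5, -1.33895614e-7,
    2.49709824e-9, 6.51711721e-7, 1.94960053e-9, -1.00361113e-8,
    -1.21206673e-5, -2.18203660e-7, 7.51269482e-9, 9.79063848e-11,
    1.25006734e-6, -1.81584736e-9, -3.52197671e-10, -3.36514630e-8,
    1.35908359e-10, 4.17032620e-10, -1.30369025e-9, 4.13908461e-10,
    9.22652254e-12, -5.08220384e-9, -2.24730961e-11, 1.17139133e-10,
    6.62154879e-10, 4.03863260e-13, 1.95087203e-12, -4.73602469e-12,
    5.12733497, -0.312788561, -0.0196701861, 9.99690870e-4,
    9.51738512e-6, -4.66426341e-7, 0.548050612, -0.00330552823,
    -0.00164119440, -5.16670694e-6, 9.52692432e-7, -0.0429223622,
    0.00500845667, 1.00601257e-6, -1.81748644e-6, -1.25813502e-3,
    -1.79330391e-4, 2.34994441e-6, 1.29735808e-4, 1.29064870e-6,
    -2.28558686e-6, -0.0369476348, 0.00162325322, -3.14279680e-5,
    2.59835559e-6, -4.77136523e-8, 8.64203390e-3, -6.87405181e-4,
    -9.13863872e-6, 5.15916806e-7, -3.59217476e-5, 3.28696511e-5,
    -7.10542454e-7, -1.24382300e-5, -7.38584400e-9, 2.20609296e-7,
    -7.32469180e-4, -1.87381964e-5, 4.80925239e-6, -8.75492040e-8,
    2.77862930e-5, -5.06004592e-6, 1.14325367e-7, 2.53016723e-6,
    -1.72857035e-8, -3.95079398e-8, -3.59413173e-7, 7.04388046e-7,
    -1.89309167e-8, -4.79768731e-7, 7.96079978e-9, 1.62897058e-9,
    3.94367674e-8, -1.18566247e-9, 3.34678041e-10, -1.15606447e-10,
    -2.80626406, 0.548712484, -0.00399428410, -9.54009191e-4,
    1.93090978e-5, -0.308806365, 0.0116952364, 4.95271903e-4,
    -1.90710882e-5, 0.00210787756, -6.98445738e-4, 2.30109073e-5,
    4.17856590e-4, -1.27043871e-5, -3.04620472e-6, 0.0514507424,
    -0.00432510997, 8.99281156e-5, -7.14663943e-7, -2.66016305e-4,
    2.63789586e-4, -7.01199003e-6, -1.06823306e-4, 3.61341136e-6,
    2.29748967e-7, 3.04788893e-4, -6.42070836e-5, 1.16257971e-6,
    7.68023384e-6, -5.47446896e-7, -3.59937910e-8, -4.36497725e-6,
    1.68737969e-7, 2.67489271e-8, 3.23926897e-9, -0.0353874123,
    -0.221201190, 0.0155126038, -2.63917279e-4, 0.0453433455,
    -0.00432943862, 1.45389826e-4, 2.17508610e-4, -6.66724702e-5,
    3.33217140e-5, -0.00226921615, 3.80261982e-4, -5.45314314e-9,
    -7.96355448e-4, 2.53458034e-5, -6.31223658e-6, 3.02122035e-4,
    -4.77403547e-6, 1.73825715e-6, -4.09087898e-7, 0.614155345,
    -0.0616755931, 0.00133374846, 0.00355375387, -5.13027851e-4,
    1.02449757e-4, -0.00148526421, -4.11469183e-5, -6.80434415e-6,
    -9.77675906e-6, 0.0882773108, -0.00301859306, 0.00104452989,
    2.47090539e-4, 0.00148348065)
}

# Primary evaluation: exponent table times coefficient vector (vectorized
# over inputs).
utci_offset_table <- function(tdb, v, d_tr, pa) {
  ex <- utci_exponent_table()
  co <- utci_coefficients()
  n <- max(length(tdb), length(v), length(d_tr), length(pa))
  tdb <- rep_len(tdb, n); v <- rep_len(v, n)
  d_tr <- rep_len(d_tr, n); pa <- rep_len(pa, n)
  tp <- outer(tdb, 0:6, `^`); vp <- outer(v, 0:6, `^`)
  dp <- outer(d_tr, 0:6, `^`); pp <- outer(pa, 0:6, `^`)
  acc <- numeric(n)
  for (r in seq_len(210L)) {
    acc <- acc + co[r] * tp[, ex[r, 1] + 1L] * vp[, ex[r, 2] + 1L] *
      dp[, ex[r, 3] + 1L] * pp[, ex[r, 4] + 1L]
  }
  acc
}

# Independent second transcription (direct expression, scalar inputs);
# used as the in-package oracle for the dual-implementation check.
utci_offset_reference <- function(tdb, v, d_tr, pa) {
  (
  0.607562052
  + (-0.0227712343) * tdb
  + (8.06470249e-4) * tdb * tdb
  + (-1.54271372e-4) * tdb^3
  + (-3.24651735e-6) * tdb^4
  + (7.32602852e-8) * tdb^5
  + (1.35959073e-9) * tdb^6
  + (-2.25836520) * v
  + 0.0880326035 * tdb * v
  + 0.00216844454 * tdb * tdb * v
  + (-1.53347087e-5) * tdb^3 * v
  + (-5.72983704e-7) * tdb^4 * v
  + (-2.55090145e-9) * tdb^5 * v
  + (-0.751269505) * v * v
  + (-0.00408350271) * tdb * v * v
  + (-5.21670675e-5) * tdb^2 * v^2
  + (1.94544667e-6) * tdb^3 * v^2
  + (1.14099531e-8) * tdb^4 * v^2
  + 0.158137256 * v^3
  + (-6.57263143e-5) * tdb * v^3
  + (2.22697524e-7) * tdb^2 * v^3
  + (-4.16117031e-8) * tdb^3 * v^3
  + (-0.0127762753) * v^4
  + (9.66891875e-6) * tdb * v^4
  + (2.52785852e-9) * tdb^2 * v^4
  + (4.56306672e-4) * v^5
  + (-1.74202546e-7) * tdb * v^5
  + (-5.91491269e-6) * v^6
  + 0.398374029 * d_tr
  + (1.83945314e-4) * tdb * d_tr
  + (-1.73754510e-4) * tdb^2 * d_tr
  + (-7.60781159e-7) * tdb^3 * d_tr
  + (3.77830287e-8) * tdb^4 * d_tr
  + (5.43079673e-10) * tdb^5 * d_tr
  + (-0.0200518269) * v * d_tr
  + (8.92859837e-4) * tdb * v * d_tr
  + (3.45433048e-6) * tdb^2 * v * d_tr
  + (-3.77925774e-7) * tdb^3 * v * d_tr
  + (-1.69699377e-9) * tdb^4 * v * d_tr
  + (1.69992415e-4) * v^2 * d_tr
  + (-4.99204314e-5) * tdb * v^2 * d_tr
  + (2.47417178e-7) * tdb^2 * v^2 * d_tr
  + (1.07596466e-8) * tdb^3 * v^2 * d_tr
  + (8.49242932e-5) * v^3 * d_tr
  + (1.35191328e-6) * tdb * v^3 * d_tr
  + (-6.21531254e-9) * tdb^2 * v^3 * d_tr
  + (-4.99410301e-6) * v^4 * d_tr
  + (-1.89489258e-8) * tdb * v^4 * d_tr
  + (8.15300114e-8) * v^5 * d_tr
  + (7.55043090e-4) * d_tr^2
  + (-5.65095215e-5) * tdb * d_tr^2
  + (-4.52166564e-7) * tdb^2 * d_tr^2
  + (2.46688878e-8) * tdb^3 * d_tr^2
  + (2.42674348e-10) * tdb^4 * d_tr^2
  + (1.54547250e-4) * v * d_tr^2
  + (5.24110970e-6) * tdb * v * d_tr^2
  + (-8.75874982e-8) * tdb^2 * v * d_tr^2
  + (-1.50743064e-9) * tdb^3 * v * d_tr^2
  + (-1.56236307e-5) * v^2 * d_tr^2
  + (-1.33895614e-7) * tdb * v^2 * d_tr^2
  + (2.49709824e-9) * tdb^2 * v^2 * d_tr^2
  + (6.51711721e-7) * v^3 * d_tr^2
  + (1.94960053e-9) * tdb * v^3 * d_tr^2
  + (-1.00361113e-8) * v^4 * d_tr^2
  + (-1.21206673e-5) * d_tr^3
  + (-2.18203660e-7) * tdb * d_tr^3
  + (7.51269482e-9) * tdb^2 * d_tr^3
  + (9.79063848e-11) * tdb^3 * d_tr^3
  + (1.25006734e-6) * v * d_tr^3
  + (-1.81584736e-9) * tdb * v * d_tr^3
  + (-3.52197671e-10) * tdb^2 * v * d_tr^3
  + (-3.36514630e-8) * v^2 * d_tr^3
  + (1.35908359e-10) * tdb * v^2 * d_tr^3
  + (4.17032620e-10) * v^3 * d_tr^3
  + (-1.30369025e-9) * d_tr^4
  + (4.13908461e-10) * tdb * d_tr^4
  + (9.22652254e-12) * tdb^2 * d_tr^4
  + (-5.08220384e-9) * v * d_tr^4
  + (-2.24730961e-11) * tdb * v * d_tr^4
  + (1.17139133e-10) * v^2 * d_tr^4
  + (6.62154879e-10) * d_tr^5
  + (4.03863260e-13) * tdb * d_tr^5
  + (1.95087203e-12) * v * d_tr^5
  + (-4.73602469e-12) * d_tr^6
  + 5.12733497 * pa
  + (-0.312788561) * tdb * pa
  + (-0.0196701861) * tdb^2 * pa
  + (9.99690870e-4) * tdb^3 * pa
  + (9.51738512e-6) * tdb^4 * pa
  + (-4.66426341e-7) * tdb^5 * pa
  + 0.548050612 * v * pa
  + (-0.00330552823) * tdb * v * pa
  + (-0.00164119440) * tdb^2 * v * pa
  + (-5.16670694e-6) * tdb^3 * v * pa
  + (9.52692432e-7) * tdb^4 * v * pa
  + (-0.0429223622) * v^2 * pa
  + 0.00500845667 * tdb * v^2 * pa
  + (1.00601257e-6) * tdb^2 * v^2 * pa
  + (-1.81748644e-6) * tdb^3 * v^2 * pa
  + (-1.25813502e-3) * v^3 * pa
  + (-1.79330391e-4) * tdb * v^3 * pa
  + (2.34994441e-6) * tdb^2 * v^3 * pa
  + (1.29735808e-4) * v^4 * pa
  + (1.29064870e-6) * tdb * v^4 * pa
  + (-2.28558686e-6) * v^5 * pa
  + (-0.0369476348) * d_tr * pa
  + 0.00162325322 * tdb * d_tr * pa
  + (-3.14279680e-5) * tdb^2 * d_tr * pa
  + (2.59835559e-6) * tdb^3 * d_tr * pa
  + (-4.77136523e-8) * tdb^4 * d_tr * pa
  + (8.64203390e-3) * v * d_tr * pa
  + (-6.87405181e-4) * tdb * v * d_tr * pa
  + (-9.13863872e-6) * tdb^2 * v * d_tr * pa
  + (5.15916806e-7) * tdb^3 * v * d_tr * pa
  + (-3.59217476e-5) * v^2 * d_tr * pa
  + (3.28696511e-5) * tdb * v^2 * d_tr * pa
  + (-7.10542454e-7) * tdb^2 * v^2 * d_tr * pa
  + (-1.24382300e-5) * v^3 * d_tr * pa
  + (-7.38584400e-9) * tdb * v^3 * d_tr * pa
  + (2.20609296e-7) * v^4 * d_tr * pa
  + (-7.32469180e-4) * d_tr^2 * pa
  + (-1.87381964e-5) * tdb * d_tr^2 * pa
  + (4.80925239e-6) * tdb^2 * d_tr^2 * pa
  + (-8.75492040e-8) * tdb^3 * d_tr^2 * pa
  + (2.77862930e-5) * v * d_tr^2 * pa
  + (-5.06004592e-6) * tdb * v * d_tr^2 * pa
  + (1.14325367e-7) * tdb^2 * v * d_tr^2 * pa
  + (2.53016723e-6) * v^2 * d_tr^2 * pa
  + (-1.72857035e-8) * tdb * v^2 * d_tr^2 * pa
  + (-3.95079398e-8) * v^3 * d_tr^2 * pa
  + (-3.59413173e-7) * d_tr^3 * pa
  + (7.04388046e-7) * tdb * d_tr^3 * pa
  + (-1.89309167e-8) * tdb^2 * d_tr^3 * pa
  + (-4.79768731e-7) * v * d_tr^3 * pa
  + (7.96079978e-9) * tdb * v * d_tr^3 * pa
  + (1.62897058e-9) * v^2 * d_tr^3 * pa
  + (3.94367674e-8) * d_tr^4 * pa
  + (-1.18566247e-9) * tdb * d_tr^4 * pa
  + (3.34678041e-10) * v * d_tr^4 * pa
  + (-1.15606447e-10) * d_tr^5 * pa
  + (-2.80626406) * pa * pa
  + 0.548712484 * tdb * pa * pa
  + (-0.00399428410) * tdb^2 * pa^2
  + (-9.54009191e-4) * tdb^3 * pa^2
  + (1.93090978e-5) * tdb^4 * pa^2
  + (-0.308806365) * v * pa^2
  + 0.0116952364 * tdb * v * pa^2
  + (4.95271903e-4) * tdb^2 * v * pa^2
  + (-1.90710882e-5) * tdb^3 * v * pa^2
  + 0.00210787756 * v^2 * pa^2
  + (-6.98445738e-4) * tdb * v^2 * pa^2
  + (2.30109073e-5) * tdb^2 * v^2 * pa^2
  + (4.17856590e-4) * v^3 * pa^2
  + (-1.27043871e-5) * tdb * v^3 * pa^2
  + (-3.04620472e-6) * v^4 * pa^2
  + 0.0514507424 * d_tr * pa^2
  + (-0.00432510997) * tdb * d_tr * pa^2
  + (8.99281156e-5) * tdb^2 * d_tr * pa^2
  + (-7.14663943e-7) * tdb^3 * d_tr * pa^2
  + (-2.66016305e-4) * v * d_tr * pa^2
  + (2.63789586e-4) * tdb * v * d_tr * pa^2
  + (-7.01199003e-6) * tdb^2 * v * d_tr * pa^2
  + (-1.06823306e-4) * v^2 * d_tr * pa^2
  + (3.61341136e-6) * tdb * v^2 * d_tr * pa^2
  + (2.29748967e-7) * v^3 * d_tr * pa^2
  + (3.04788893e-4) * d_tr^2 * pa^2
  + (-6.42070836e-5) * tdb * d_tr^2 * pa^2
  + (1.16257971e-6) * tdb^2 * d_tr^2 * pa^2
  + (7.68023384e-6) * v * d_tr^2 * pa^2
  + (-5.47446896e-7) * tdb * v * d_tr^2 * pa^2
  + (-3.59937910e-8) * v^2 * d_tr^2 * pa^2
  + (-4.36497725e-6) * d_tr^3 * pa^2
  + (1.68737969e-7) * tdb * d_tr^3 * pa^2
  + (2.67489271e-8) * v * d_tr^3 * pa^2
  + (3.23926897e-9) * d_tr^4 * pa^2
  + (-0.0353874123) * pa^3
  + (-0.221201190) * tdb * pa^3
  + 0.0155126038 * tdb^2 * pa^3
  + (-2.63917279e-4) * tdb^3 * pa^3
  + 0.0453433455 * v * pa^3
  + (-0.00432943862) * tdb * v * pa^3
  + (1.45389826e-4) * tdb^2 * v * pa^3
  + (2.17508610e-4) * v^2 * pa^3
  + (-6.66724702e-5) * tdb * v^2 * pa^3
  + (3.33217140e-5) * v^3 * pa^3
  + (-0.00226921615) * d_tr * pa^3
  + (3.80261982e-4) * tdb * d_tr * pa^3
  + (-5.45314314e-9) * tdb^2 * d_tr * pa^3
  + (-7.96355448e-4) * v * d_tr * pa^3
  + (2.53458034e-5) * tdb * v * d_tr * pa^3
  + (-6.31223658e-6) * v^2 * d_tr * pa^3
  + (3.02122035e-4) * d_tr^2 * pa^3
  + (-4.77403547e-6) * tdb * d_tr^2 * pa^3
  + (1.73825715e-6) * v * d_tr^2 * pa^3
  + (-4.09087898e-7) * d_tr^3 * pa^3
  + 0.614155345 * pa^4
  + (-0.0616755931) * tdb * pa^4
  + 0.00133374846 * tdb^2 * pa^4
  + 0.00355375387 * v * pa^4
  + (-5.13027851e-4) * tdb * v * pa^4
  + (1.02449757e-4) * v^2 * pa^4
  + (-0.00148526421) * d_tr * pa^4
  + (-4.11469183e-5) * tdb * d_tr * pa^4
  + (-6.80434415e-6) * v * d_tr * pa^4
  + (-9.77675906e-6) * d_tr^2 * pa^4
  + 0.0882773108 * pa^5
  + (-0.00301859306) * tdb * pa^5
  + 0.00104452989 * v * pa^5
  + (2.47090539e-4) * d_tr * pa^5
  + 0.00148348065 * pa^6
  )
}

#' Universal Thermal Climate Index (operational polynomial approximation)
#'
#' Evaluates the published operational 6th-order polynomial approximation
#' of the UTCI equivalent temperature.  Inputs must lie inside the
#' operational validity ranges; out-of-range input raises an error naming
#' the violated bound (no silent clamping here -- clamping happens only in
#' the scenario layer of [utci_series()]).
#'
#' @param t_air Air temperature, degC, in `[-50, 50]`.
#' @param v Wind speed at 10 m, m/s, in `[0.5, 17]`.
#' @param e Water vapour pressure, hPa (`e/10` kPa must be <= 5).
#' @param t_mrt Mean radiant temperature, degC; `t_mrt - t_air` must lie in
#'   `[-30, 70]`.
#' @return UTCI in degC (vectorized over the inputs).
#' @export
utci <- function(t_air, v, e, t_mrt) {
  if (any(t_air < -50 | t_air > 50))
    stop("air temperature outside the UTCI validity range [-50, 50] degC")
  if (any(v < 0.5 | v > 17))
    stop("wind speed outside the UTCI validity range [0.5, 17] m/s")
  d_tr <- t_mrt - t_air
  if (any(d_tr < -30 | d_tr > 70))
    stop("Tmrt - T outside the UTCI validity range [-30, 70] degC")
  pa <- e / 10
  if (any(pa < 0 | pa > 5))
    stop("vapour pressure outside the UTCI validity range [0, 50] hPa")
  t_air + utci_offset_table(t_air, v, d_tr, pa)
}

#' Constant-wind UTCI scenario
#'
#' Wind below the 0.5 m/s validity floor (also the lowest scenario of
#' interest) is raised to 0.5 with a warning.
#'
#' @param wind_speed Constant wind speed in m/s.
#' @param label Scenario label; default derived from the wind speed.
#' @return List of class `utci_scenario`.
#' @export
utci_scenario <- function(wind_speed, label = NULL) {
  if (wind_speed < 0.5) {
    warning("wind speed ", wind_speed,
            " m/s below the UTCI validity floor; raised to 0.5 m/s")
    wind_speed <- 0.5
  }
  if (wind_speed > 17) stop("wind speed above the UTCI validity range")
  if (is.null(label)) label <- sprintf("%g m/s", wind_speed)
  structure(list(wind_speed = wind_speed, label = label),
            class = "utci_scenario")
}

#' Monthly UTCI series under a constant wind scenario
#'
#' Per month: cloudiness from sunshine, mid-month solar altitude, absorbed
#' solar radiation, long-wave terms, mean radiant temperature, then the
#' UTCI polynomial at the scenario wind.  Vapour pressure comes from the
#' dataset when present, otherwise from `rh_proxy * e_sat(T)` (Tetens).
#' Months violating a validity range are flagged and set `NA` rather than
#' aborting the series.
#'
#' @param dataset Named list of aligned `monthly_series` with `sunshine`,
#'   `precipitation`, `temperature` and optionally `vapour_pressure`.
#' @param scenario A [utci_scenario()] or a wind speed in m/s.
#' @param rh_proxy Relative-humidity constant used when vapour pressure is
#'   absent (default 0.7).
#' @param latitude Site latitude, degrees.
#' @param irc Clothing coefficient passed to [mrt()].
#' @return A `monthly_series` of variable `"utci"` with attributes `valid`
#'   (logical per month) and `scenario`.
#' @export
utci_series <- function(dataset, scenario = 0.5, rh_proxy = 0.7,
                        latitude = 51.1, irc = 1.15) {
  if (!inherits(scenario, "utci_scenario")) scenario <- utci_scenario(scenario)
  temp <- dataset$temperature; sun <- dataset$sunshine
  if (is.null(temp) || is.null(sun))
    stop("dataset must contain temperature and sunshine series")
  months <- series_months(temp)
  n <- length(temp$values)
  e <- if (!is.null(dataset$vapour_pressure)) dataset$vapour_pressure$values
       else rh_proxy * tetens_saturation_vp(temp$values)
  vals <- rep(NA_real_, n); valid <- logical(n)
  for (t in seq_len(n)) {
    vals[t] <- tryCatch({
      ncl <- cloudiness_from_sunshine(max(sun$values[t], 0), months[t],
                                      latitude)
      hsl <- max(sun_altitude_midmonth(months[t], latitude), 0)
      r_abs <- absorbed_radiation_solalt(ncl, hsl)
      lw <- longwave_terms(temp$values[t], e[t], ncl)
      tmrt <- mrt(r_abs, lw$Lg, lw$La, irc = irc)
      utci(temp$values[t], scenario$wind_speed, e[t], tmrt)
    }, error = function(err) NA_real_)
    valid[t] <- !is.na(vals[t])
  }
  out <- monthly_series(ifelse(is.na(vals), 0, vals), temp$start_year,
                        temp$start_month, "utci")
  out$values[!valid] <- NA_real_
  class(out) <- "monthly_series"
  attr(out, "valid") <- valid
  attr(out, "scenario") <- scenario$label
  out
}

#' Compare two aligned series: MSE, means and density overlap
#'
#' @param a,b Aligned `monthly_series` or numeric vectors of equal length
#'   (months flagged `NA` in either are dropped pairwise).
#' @param bins Number of histogram bins for the density-overlap measure.
#' @return List with `mse`, `mean_a`, `mean_b` and `pdf_overlap`
#'   (common-grid histogram intersection in `[0, 1]`).
#' @export
compare_series <- function(a, b, bins = 30L) {
  va <- if (inherits(a, "monthly_series")) a$values else as.numeric(a)
  vb <- if (inherits(b, "monthly_series")) b$values else as.numeric(b)
  if (length(va) != length(vb))
    stop("series lengths differ: ", length(va), " vs ", length(vb))
  keep <- !(is.na(va) | is.na(vb))
  va <- va[keep]; vb <- vb[keep]
  rng <- range(c(va, vb))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  ha <- graphics::hist(va, breaks = brk, plot = FALSE)$counts / length(va)
  hb <- graphics::hist(vb, breaks = brk, plot = FALSE)$counts / length(vb)
  list(mse = mean((va - vb)^2), mean_a = mean(va), mean_b = mean(vb),
       pdf_overlap = sum(pmin(ha, hb)))
}
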