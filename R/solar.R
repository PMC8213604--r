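# Day-of-year of the 15th of each month (non-leap calendar).
mid_month_doy <- function(month) {
  month <- as.integer(month)
  if (any(month < 1L | month > 12L)) stop("invalid month: must be in 1..12")
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L,
                        30L)))
  cum[month] + 15L
}

days_in_month <- function(month) {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
}

#' Solar declination from the standard day-angle formula
#' @param doy Day of year (1..365).
#' @return Declination in degrees.
#' @export
solar_declination <- function(doy) {
  23.45 * sin(2 * pi * (284 + doy) / 365)
}

#' Solar altitude at solar noon on the 15th of a month
#'
#' The "middle position" of the Sun for monthly data: altitude
#' `90 - |latitude - declination|` degrees at solar noon on the 15th.
#'
#' @param month Calendar month (1..12).
#' @param latitude Site latitude in degrees (default 51.1, Wroclaw).
#' @return Solar altitude in degrees.
#' @export
sun_altitude_midmonth <- function(month, latitude = 51.1) {
  dec <- solar_declination(mid_month_doy(month))
  90 - abs(latitude - dec)
}

#' Astronomical day length on the 15th of a month
#'
#' Standard sunrise equation: `cos H0 = -tan(lat) tan(dec)`; day length is
#' `2 H0 / 15` hours.
#'
#' @inheritParams sun_altitude_midmonth
#' @return Day length in hours.
#' @export
day_length_hours <- function(month, latitude = 51.1) {
  dec <- solar_declination(mid_month_doy(month))
  ch <- -tan(latitude * pi / 180) * tan(dec * pi / 180)
  ch <- pmin(1, pmax(-1, ch))
  2 * acos(ch) * 180 / pi / 15
}

#' Astronomical maximum monthly sunshine duration
#'
#' Mid-month day length integrated over the month (day length on the 15th
#' times the number of days, non-leap calendar): the cloudless upper bound
#' on the monthly sunshine sum.
#'
#' @inheritParams sun_altitude_midmonth
#' @return Hours per month.
#' @export
max_monthly_sunshine <- function(month, latitude = 51.1) {
  day_length_hours(month, latitude) * days_in_month(as.integer(month))
}

#' Cloudiness inferred from monthly sunshine duration
#'
#' The standard sunshine-cloudiness complement: `N = 100 (1 - s / S0)`
#' percent, with `S0` the astronomical maximum monthly sunshine at the site
#' latitude, clamped to `[0, 100]`.
#'
#' @param s Monthly sunshine duration (h/month, >= 0).
#' @param month Calendar month (1..12).
#' @param latitude Site latitude in degrees.
#' @return Cloudiness in percent.
#' @export
cloudiness_from_sunshine <- function(s, month, latitude = 51.1) {
  if (any(s < 0)) stop("sunshine duration must be >= 0")
  s0 <- max_monthly_sunshine(month, latitude)
  pmin(100, pmax(0, 100 * (1 - s / s0)))
}
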