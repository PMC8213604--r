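#' Monthly time series with calendar index
#'
#' A `monthly_series` is an ordered, gap-free sequence of monthly values with
#' a calendar anchor and a variable tag.  One value represents one whole
#' month (sum or mean, depending on the variable), timestamped at month
#' start; month index 1 is January.
#'
#' @param values Numeric vector, one value per month, no missing entries.
#' @param start_year Calendar year of the first value.
#' @param start_month Calendar month (1--12) of the first value.
#' @param variable One of `"sunshine"` (h/month), `"precipitation"`
#'   (mm/month), `"temperature"` (degC), `"vapour_pressure"` (hPa) or
#'   `"utci"` (degC).
#' @return An object of class `monthly_series`.
#' @export
monthly_series <- function(values, start_year, start_month = 1L,
                           variable = c("sunshine", "precipitation",
                                        "temperature", "vapour_pressure",
                                        "utci")) {
  variable <- match.arg(variable)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must contain at least one month")
  if (anyNA(values)) stop("'values' must not contain missing entries")
  if (!is.numeric(start_year) || length(start_year) != 1L)
    stop("'start_year' must be a single year")
  start_month <- as.integer(start_month)
  if (start_month < 1L || start_month > 12L)
    stop("'start_month' must be in 1..12")
  structure(list(values = values,
                 start_year = as.integer(start_year),
                 start_month = start_month,
                 variable = variable),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %s: %d months from %d-%02d\n",
              x$variable, length(x$values), x$start_year, x$start_month))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.monthly_series <- function(x) length(x$values)

#' Calendar months (1 = January) of each value in a series
#' @param x A `monthly_series`.
#' @return Integer vector of calendar months, same length as the series.
#' @export
series_months <- function(x) {
  ((x$start_month - 1L + seq_along(x$values) - 1L) %% 12L) + 1L
}

#' Calendar years of each value in a series
#' @param x A `monthly_series`.
#' @return Integer vector of calendar years.
#' @export
series_years <- function(x) {
  x$start_year + (x$start_month - 1L + seq_along(x$values) - 1L) %/% 12L
}

#' Drop months from both ends of a series, keeping the calendar anchor right
#' @param x A `monthly_series`.
#' @param head Months removed from the start.
#' @param tail Months removed from the end.
#' @return The trimmed `monthly_series`.
#' @export
trim_series <- function(x, head = 0L, tail = 0L) {
  n <- length(x$values)
  if (head + tail >= n) stop("trimming removes the whole series")
  keep <- seq.int(head + 1L, n - tail)
  m0 <- x$start_month - 1L + head
  monthly_series(x$values[keep],
                 start_year = x$start_year + m0 %/% 12L,
                 start_month = (m0 %% 12L) + 1L,
                 variable = x$variable)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(year = series_years(x), month = series_months(x),
             value = x$values)
}

canonical_columns <- c(sunshine = "sunshine_h", precipitation = "precip_mm",
                       temperature = "temp_c", vapour_pressure = "vapour_hpa")

#' Write a three-variable monthly dataset to the canonical CSV dialect
#'
#' Header `year,month,sunshine_h,precip_mm,temp_c[,vapour_hpa][,wind_ms]`,
#' UTF-8, '.' decimal separator.
#'
#' @param dataset Named list of aligned `monthly_series` containing at least
#'   `sunshine`, `precipitation` and `temperature`; optionally
#'   `vapour_pressure`.
#' @param path Output file path.
#' @param wind_ms Optional constant wind speed written as a `wind_ms` column.
#' @return `path`, invisibly.
#' @export
write_monthly_csv <- function(dataset, path, wind_ms = NULL) {
  need <- c("sunshine", "precipitation", "temperature")
  if (!all(need %in% names(dataset)))
    stop("dataset must contain sunshine, precipitation and temperature")
  s <- dataset$sunshine
  n <- length(s$values)
  for (v in dataset) {
    if (length(v$values) != n || v$start_year != s$start_year ||
        v$start_month != s$start_month)
      stop("all series in the dataset must be aligned")
  }
  df <- data.frame(year = series_years(s), month = series_months(s),
                   sunshine_h = dataset$sunshine$values,
                   precip_mm = dataset$precipitation$values,
                   temp_c = dataset$temperature$values)
  if (!is.null(dataset$vapour_pressure))
    df$vapour_hpa <- dataset$vapour_pressure$values
  if (!is.null(wind_ms)) df$wind_ms <- rep_len(wind_ms, n)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly dataset from the canonical CSV dialect
#'
#' @param path CSV file with header
#'   `year,month,sunshine_h,precip_mm,temp_c[,vapour_hpa][,wind_ms]`.
#' @return Named list of `monthly_series` (plus `wind_ms` scalar attribute
#'   when present).
#' @export
read_monthly_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "month", "sunshine_h", "precip_mm", "temp_c")
  if (!all(need %in% names(df)))
    stop("missing canonical columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  # months must be consecutive
  idx <- (df$year - df$year[1]) * 12 + (df$month - df$month[1])
  if (!all(idx == seq_along(idx) - 1L))
    stop("months are not consecutive in ", path)
  mk <- function(col, var) monthly_series(df[[col]], df$year[1], df$month[1], var)
  out <- list(sunshine = mk("sunshine_h", "sunshine"),
              precipitation = mk("precip_mm", "precipitation"),
              temperature = mk("temp_c", "temperature"))
  if ("vapour_hpa" %in% names(df))
    out$vapour_pressure <- mk("vapour_hpa", "vapour_pressure")
  if ("wind_ms" %in% names(df)) attr(out, "wind_ms") <- df$wind_ms[1]
  out
}
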