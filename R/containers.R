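# Core data containers: gridded monthly fields and band time series.

#' Gridded monthly field
#'
#' Monthly values on a regular lat/lon grid: a `n_lat x n_lon x n_time` array
#' with cell-center coordinate vectors and a `(year, month)` time table.
#' Missing cells (e.g. land) are `NA`.
#'
#' @param data numeric array, dim `c(length(lat), length(lon), nrow(time))`.
#' @param lat,lon cell-center coordinates, strictly increasing, degrees
#'   north/east.
#' @param time data frame with integer columns `year` and `month` (1--12),
#'   strictly increasing in time.
#' @param variable short variable name (e.g. `"sst"`).
#' @param units physical units (e.g. `"degC"`).
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(data, lat, lon, time, variable, units) {
  time <- as.data.frame(time)
  stopifnot(all(c("year", "month") %in% names(time)))
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0))
    stop("grid_field: lat and lon must be strictly increasing")
  if (any(time$month < 1 | time$month > 12))
    stop("grid_field: month must be in 1..12")
  key <- time$year * 12 + time$month
  if (any(diff(key) <= 0))
    stop("grid_field: time must be strictly increasing")
  data <- array(as.double(data),
                dim = c(length(lat), length(lon), nrow(time)))
  structure(list(data = data, lat = as.double(lat), lon = as.double(lon),
                 time = data.frame(year = as.integer(time$year),
                                   month = as.integer(time$month)),
                 variable = as.character(variable),
                 units = as.character(units)),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s], %d x %d cells, %d months (%d-%02d .. %d-%02d)\n",
              x$variable, x$units, length(x$lat), length(x$lon), nrow(x$time),
              x$time$year[1], x$time$month[1],
              x$time$year[nrow(x$time)], x$time$month[nrow(x$time)]))
  invisible(x)
}

# (year, month) sequence helper, inclusive
month_seq <- function(year_from, year_to) {
  data.frame(year = rep(year_from:year_to, each = 12L), month = rep(1:12, year_to - year_from + 1L))
}

#' Monthly band series
#'
#' An ordered `(year, month) -> value` series with gaps allowed (`NA` values
#' or absent months), at most one value per month.
#'
#' @param year,month integer vectors, jointly strictly increasing.
#' @param value numeric values (may be `NA`).
#' @param variable,units,band metadata carried as attributes.
#' @return a data frame of class `monthly_series` with columns
#'   `year`, `month`, `value`.
#' @export
monthly_series <- function(year, month, value, variable = "value",
                           units = "", band = NA_integer_) {
  stopifnot(length(year) == length(month), length(year) == length(value))
  if (any(month < 1 | month > 12)) stop("monthly_series: month must be in 1..12")
  key <- year * 12 + month
  if (anyDuplicated(key)) stop("monthly_series: duplicate (year, month)")
  o <- order(key)
  out <- data.frame(year = as.integer(year[o]), month = as.integer(month[o]),
                    value = as.double(value[o]))
  structure(out, variable = variable, units = units, band = band,
            class = c("monthly_series", "data.frame"))
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %s [%s], band %s, %d months, %d missing\n",
              attr(x, "variable"), attr(x, "units"),
              as.character(attr(x, "band")), nrow(x), sum(is.na(x$value))))
  invisible(x)
}

# Fill a monthly series onto the complete month grid spanning its range;
# returns data frame with NA where absent.
regularize_months <- function(series) {
  first <- series$year[1] * 12L + series$month[1]
  last <- series$year[nrow(series)] * 12L + series$month[nrow(series)]
  key <- seq(first, last)
  year <- (key - 1L) %/% 12L
  month <- key - year * 12L
  value <- rep(NA_real_, length(key))
  value[match(series$year * 12L + series$month, key)] <- series$value
  data.frame(year = year, month = month, value = value)
}
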