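# Self-describing file formats for gridded fields, coast geometry, trawl
# records and tidy series tables. Gridded fields use a CF-like JSON container
# (coordinate variables lat/lon/time, units attributes, null as the missing
# value sentinel): text-only and lossless on round trip.

#' Write / read a gridded monthly field
#'
#' The on-disk format is a self-describing JSON container with coordinate
#' variables (`lat`, `lon`, `time$year`, `time$month`), `variable` and `units`
#' attributes, and the data flattened in column-major order with `null` for
#' missing cells. Numeric values are serialised at full precision, so a
#' write/read round trip is lossless.
#'
#' @param field a [grid_field()].
#' @param path file path.
#' @return `read_gridfield` returns a [grid_field()];
#'   `write_gridfield` returns `path` invisibly.
#' @export
write_gridfield <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  obj <- list(
    format = "pelagicshift-gridfield-1",
    variable = field$variable,
    units = field$units,
    dims = c(n_lat = length(field$lat), n_lon = length(field$lon),
             n_time = nrow(field$time)),
    lat = field$lat, lon = field$lon,
    time = list(year = field$time$year, month = field$time$month),
    missing_value = "null",
    data = as.vector(field$data)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_gridfield
#' @export
read_gridfield <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (a in c("variable", "units", "lat", "lon", "time", "data"))
    if (is.null(obj[[a]]))
      stop("read_gridfield: missing required attribute '", a, "' in ", path)
  if (is.null(obj$time$year) || is.null(obj$time$month))
    stop("read_gridfield: missing time axis (year/month) in ", path)
  grid_field(obj$data, obj$lat, obj$lon,
             data.frame(year = obj$time$year, month = obj$time$month),
             obj$variable, obj$units)
}

#' Write / read coast geometry
#'
#' Each polyline is stored as a two-column delimited `(lat, lon)` vertex
#' table; the two tables and the ocean side live in one JSON document.
#'
#' @param coast a [coast_geometry()].
#' @param path file path.
#' @export
write_coast <- function(coast, path) {
  stopifnot(inherits(coast, "coast_geometry"))
  obj <- list(format = "pelagicshift-coast-1",
              ocean_side = coast$ocean_side,
              coastline = as.data.frame(coast$coastline),
              isobath200 = as.data.frame(coast$isobath200))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_coast
#' @export
read_coast <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coast_geometry(obj$coastline, obj$isobath200, obj$ocean_side)
}

#' Write / read trawl records
#'
#' Delimited table with header `year, date, lat, lon` followed by one numeric
#' catch column per species (0 = absent). Dates are ISO-8601. Unknown species
#' columns are preserved. Latitudes outside `[-90, 90]` or longitudes outside
#' `[-180, 180)` are rejected; an empty table reads as an empty data frame
#' with a warning.
#'
#' @param trawls data frame of trawl records.
#' @param path file path (CSV).
#' @export
write_trawls <- function(trawls, path) {
  stopifnot(all(c("year", "date", "lat", "lon") %in% names(trawls)))
  utils::write.csv(trawls, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trawls
#' @export
read_trawls <- function(path) {
  trawls <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(trawls) == 0) {
    warning("read_trawls: empty trawl table in ", path)
    return(trawls)
  }
  need <- c("year", "date", "lat", "lon")
  miss <- setdiff(need, names(trawls))
  if (length(miss))
    stop("read_trawls: missing required column(s): ", paste(miss, collapse = ", "))
  if (any(abs(trawls$lat) > 90))
    stop("read_trawls: latitude outside [-90, 90]")
  if (any(trawls$lon < -180 | trawls$lon >= 180))
    stop("read_trawls: longitude outside [-180, 180)")
  if (any(!grepl("^\\d{4}-\\d{2}-\\d{2}$", trawls$date)))
    stop("read_trawls: dates must be ISO-8601 (YYYY-MM-DD)")
  trawls
}

#' Write a monthly or yearly series as a tidy delimited table
#'
#' @param series a [monthly_series()] or plain data frame.
#' @param path file path (CSV).
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)
  a <- attributes(series)
  if (!is.null(a$variable)) df$variable <- a$variable
  if (!is.null(a$band) && !is.na(a$band)) df$band <- a$band
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
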