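# Two-period SST climatologies, isotherm tracing, and coastal/offshore
# displacement between periods.

#' Period climatology of a gridded field
#'
#' Cell-wise mean over all months whose year falls in `years`. Cells with
#' fewer than `min_years` distinct contributing years are set missing.
#'
#' @param field a [grid_field()].
#' @param years integer years of the period (e.g. `1982:2001`).
#' @param min_years minimum contributing years per cell (default 10).
#' @return an object of class `period_climatology`: list with matrix `mean`,
#'   `lat`, `lon`, `years`, and the field metadata.
#' @export
period_mean <- function(field, years, min_years = 10) {
  stopifnot(inherits(field, "grid_field"))
  keep <- field$time$year %in% years
  if (!any(keep))
    stop("period_mean: field has no months in years ",
         min(years), "-", max(years))
  ncell <- length(field$lat) * length(field$lon)
  flat <- matrix(field$data, nrow = ncell)[, keep, drop = FALSE]
  yr <- field$time$year[keep]
  m <- rowMeans(flat, na.rm = TRUE)
  # distinct years with at least one non-missing month, per cell
  ok_year <- vapply(sort(unique(yr)), function(y)
    rowSums(!is.na(flat[, yr == y, drop = FALSE])) > 0,
    logical(ncell))
  ny <- rowSums(matrix(ok_year, nrow = ncell))
  m[ny < min_years] <- NA_real_
  m[!is.finite(m)] <- NA_real_
  structure(list(mean = matrix(m, length(field$lat), length(field$lon)),
                 lat = field$lat, lon = field$lon, years = range(years),
                 variable = field$variable, units = field$units),
            class = "period_climatology")
}

#' Trace a surface isotherm through a climatology
#'
#' For each longitude column intersecting `band_mask`, scans south to north
#' for sign changes of `clim - temperature` between adjacent in-mask cells and
#' linearly interpolates the crossing latitude. The first (southernmost)
#' crossing is recorded; columns with more than one crossing are flagged
#' (`multiple`), surfacing any non-monotone structure instead of guessing.
#'
#' @param clim a [period_mean()] climatology.
#' @param temperature isotherm value, same units as the climatology.
#' @param band_mask logical matrix restricting the search (e.g. the coastal
#'   strip); defaults to all non-missing cells.
#' @return data frame of class `isotherm_trace` with columns `lon`, `lat`,
#'   `multiple`, and attributes `temperature`, `units`.
#' @export
trace_isotherm <- function(clim, temperature, band_mask = NULL) {
  stopifnot(inherits(clim, "period_climatology"))
  z <- clim$mean
  if (is.null(band_mask)) band_mask <- !is.na(z)
  if (!all(dim(band_mask) == dim(z)))
    stop("trace_isotherm: band_mask shape does not match climatology")
  lats <- clim$lat
  out_lon <- numeric(0); out_lat <- numeric(0); out_mult <- logical(0)
  for (j in seq_along(clim$lon)) {
    ok <- band_mask[, j] & !is.na(z[, j])
    if (sum(ok) < 2) next
    v <- z[, j] - temperature
    # adjacent grid rows, both in mask and defined
    i <- which(ok[-length(ok)] & ok[-1])
    cross <- i[v[i] * v[i + 1] < 0 | v[i] == 0]
    if (!length(cross)) next
    k <- cross[1]
    lat_hat <- if (v[k] == 0) lats[k] else
      lats[k] + (lats[k + 1] - lats[k]) * (0 - v[k]) / (v[k + 1] - v[k])
    out_lon <- c(out_lon, clim$lon[j])
    out_lat <- c(out_lat, lat_hat)
    out_mult <- c(out_mult, length(cross) > 1)
  }
  if (!length(out_lon))
    stop("trace_isotherm: isotherm ", temperature, " ", clim$units,
         " not found anywhere in the band")
  structure(data.frame(lon = out_lon, lat = out_lat, multiple = out_mult),
            temperature = temperature, units = clim$units,
            class = c("isotherm_trace", "data.frame"))
}

#' Meridional displacement between two isotherm traces
#'
#' Mean, over longitude columns common to both traces, of the meridional
#' great-circle distance between the crossing latitudes, signed positive when
#' trace B lies north of trace A. At least 3 common columns are required.
#'
#' @param traceA,traceB [trace_isotherm()] results for the same temperature.
#' @return list with `km` (signed mean displacement), `n` (common columns).
#' @export
displacement <- function(traceA, traceB) {
  m <- match(round(traceA$lon, 9), round(traceB$lon, 9))
  ok <- !is.na(m)
  if (sum(ok) < 3)
    stop("displacement: fewer than 3 common longitude columns")
  dlat <- traceB$lat[m[ok]] - traceA$lat[ok]
  list(km = mean(dlat) * KM_PER_DEG_LAT, n = sum(ok))
}

#' Inter-period anomaly map
#'
#' Cell-wise difference `climB - climA` of two climatologies on the same grid.
#'
#' @param climB,climA [period_mean()] climatologies (B minus A).
#' @return matrix of differences.
#' @export
anomaly_map <- function(climB, climA) {
  stopifnot(inherits(climA, "period_climatology"),
            inherits(climB, "period_climatology"))
  if (!isTRUE(all.equal(climA$lat, climB$lat)) ||
      !isTRUE(all.equal(climA$lon, climB$lon)))
    stop("anomaly_map: climatologies are not on the same grid")
  climB$mean - climA$mean
}

#' Coastal and offshore isotherm displacement between two periods
#'
#' Convenience wrapper: traces each requested isotherm through both
#' climatologies in a coastal band (within `coastal_km` of the coast) and an
#' offshore band (`coastal_km` to `offshore_km`), and reports the signed
#' meridional displacement (period B relative to period A) in each band.
#'
#' @param climA,climB [period_mean()] climatologies (earlier, later).
#' @param temperatures isotherm values (default `c(18.5, 20, 22, 24)`).
#' @param dist result of [distance_to_coast_field()] on the same grid.
#' @param coastal_km,offshore_km band limits in km (defaults 100 and 300).
#' @return data frame with one row per isotherm: `temperature`, `coastal_km`,
#'   `offshore_km`, `n_coastal`, `n_offshore` (`NA` where a trace is missing
#'   in a band).
#' @export
isotherm_shift <- function(climA, climB, temperatures = c(18.5, 20, 22, 24),
                           dist, coastal_km = 100, offshore_km = 300) {
  masks <- list(
    coastal = dist$ocean & !is.na(dist$distance_km) &
      dist$distance_km <= coastal_km,
    offshore = dist$ocean & !is.na(dist$distance_km) &
      dist$distance_km > coastal_km & dist$distance_km <= offshore_km)
  one <- function(temp, mask) {
    res <- tryCatch({
      ta <- trace_isotherm(climA, temp, mask)
      tb <- trace_isotherm(climB, temp, mask)
      displacement(ta, tb)
    }, error = function(e) NULL)
    if (is.null(res)) c(NA_real_, NA_real_) else c(res$km, res$n)
  }
  co <- vapply(temperatures, one, numeric(2), mask = masks$coastal)
  off <- vapply(temperatures, one, numeric(2), mask = masks$offshore)
  data.frame(temperature = temperatures,
             coastal_km = co[1, ], offshore_km = off[1, ],
             n_coastal = co[2, ], n_offshore = off[2, ])
}
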