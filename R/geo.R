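# Geometry of the coastal domain: spherical distances, distance-to-coast
# fields, coastal strips, latitude bands and area-averaged series.

#' Mean Earth radius (km) of the spherical Earth model
#'
#' All great-circle distances in the package use a sphere of radius 6371 km,
#' adequate at the 30--300 km scales of coastal-strip analysis. One degree of
#' meridian is `pi * 6371 / 180` = 111.195 km.
#' @export
EARTH_RADIUS_KM <- 6371

#' Kilometres per degree of latitude on the spherical Earth
#' @export
KM_PER_DEG_LAT <- pi * EARTH_RADIUS_KM / 180

#' Regular latitude/longitude grid specification
#'
#' Describes a regular lat/lon grid with cell-center registration: cells tile
#' `[lat_min, lat_max] x [lon_min, lon_max]` and values live at cell centers.
#'
#' @param lat_min,lat_max southern/northern grid edges, degrees north.
#' @param lon_min,lon_max western/eastern grid edges, degrees east
#'   (in `[-180, 180)`).
#' @param resolution cell size in degrees (same in both directions).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 32, -22, -10, 0.25)
#' length(grid_lat(g))  # 88 cells
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution) {
  stopifnot(is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(lon_min), is.numeric(lon_max),
            is.numeric(resolution), length(resolution) == 1L)
  if (lat_max <= lat_min) stop("grid_spec: lat_max must exceed lat_min")
  if (lon_max <= lon_min) stop("grid_spec: lon_max must exceed lon_min")
  if (resolution <= 0) stop("grid_spec: resolution must be positive")
  n_lat <- (lat_max - lat_min) / resolution
  n_lon <- (lon_max - lon_min) / resolution
  if (abs(n_lat - round(n_lat)) > 1e-6 || abs(n_lon - round(n_lon)) > 1e-6)
    stop("grid_spec: extent is not an integral number of cells at resolution ",
         resolution)
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 resolution = resolution,
                 n_lat = as.integer(round(n_lat)),
                 n_lon = as.integer(round(n_lon)),
                 registration = "cell-center"),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param spec a `grid_spec`.
#' @export
grid_lat <- function(spec) {
  spec$lat_min + spec$resolution * (seq_len(spec$n_lat) - 0.5)
}

#' @rdname grid_spec
#' @export
grid_lon <- function(spec) {
  spec$lon_min + spec$resolution * (seq_len(spec$n_lon) - 0.5)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g..%g degN x %g..%g degE @ %g deg (%d x %d cells)\n",
              x$lat_min, x$lat_max, x$lon_min, x$lon_max, x$resolution,
              x$n_lat, x$n_lon))
  invisible(x)
}

#' Coastline and 200 m isobath geometry
#'
#' Holds the coastline and the 200 m isobath as south-to-north ordered vertex
#' polylines, plus which side of the coastline is ocean (west for Northwest
#' Africa). Latitudes must be strictly increasing along each polyline, so the
#' polylines can be treated as single-valued functions lon(lat). The isobath
#' must lie on the ocean side of the coastline at every shared latitude.
#'
#' @param coastline two-column matrix or data frame `(lat, lon)`.
#' @param isobath200 two-column matrix or data frame `(lat, lon)`.
#' @param ocean_side `"west"` or `"east"` of the coastline.
#' @return An object of class `coast_geometry`.
#' @export
coast_geometry <- function(coastline, isobath200, ocean_side = "west") {
  as_poly <- function(p, what) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("coast_geometry: ", what, " needs 2 columns (lat, lon)")
    storage.mode(p) <- "double"
    dimnames(p) <- list(NULL, c("lat", "lon"))
    if (nrow(p) < 2L) stop("coast_geometry: ", what, " needs at least 2 vertices")
    if (any(diff(p[, "lat"]) <= 0))
      stop("coast_geometry: ", what, " latitudes must be strictly increasing")
    p
  }
  ocean_side <- match.arg(ocean_side, c("west", "east"))
  coastline <- as_poly(coastline, "coastline")
  isobath200 <- as_poly(isobath200, "isobath200")
  lo <- max(coastline[1, "lat"], isobath200[1, "lat"])
  hi <- min(coastline[nrow(coastline), "lat"], isobath200[nrow(isobath200), "lat"])
  if (hi > lo) {
    lats <- seq(lo, hi, length.out = 25)
    dlon <- polyline_lon_at(isobath200, lats) - polyline_lon_at(coastline, lats)
    bad <- if (ocean_side == "west") any(dlon >= 0) else any(dlon <= 0)
    if (bad)
      stop("coast_geometry: isobath200 must lie on the ocean (", ocean_side,
           ") side of the coastline at every shared latitude")
  }
  structure(list(coastline = coastline, isobath200 = isobath200,
                 ocean_side = ocean_side),
            class = "coast_geometry")
}

#' @export
print.coast_geometry <- function(x, ...) {
  cat(sprintf("<coast_geometry> coastline %d vertices (%g..%g degN), isobath200 %d vertices, ocean to the %s\n",
              nrow(x$coastline), x$coastline[1, "lat"],
              x$coastline[nrow(x$coastline), "lat"],
              nrow(x$isobath200), x$ocean_side))
  invisible(x)
}

# Longitude of a south->north polyline at given latitudes (linear
# interpolation); errors outside the latitude span.
polyline_lon_at <- function(poly, lat) {
  rng <- range(poly[, "lat"])
  if (any(lat < rng[1] - 1e-9 | lat > rng[2] + 1e-9))
    stop("latitude outside polyline span [", rng[1], ", ", rng[2], "]")
  stats::approx(poly[, "lat"], poly[, "lon"], xout = lat, rule = 2)$y
}

#' Latitudinal analysis band
#'
#' One of the latitude bands used to partition the coastal strip. The five
#' default bands mirror the study's areas 1--5 from north to south; note that
#' band 3 (around Cape Blanc) overlaps band 4, so bands are independent
#' selections, never assumed disjoint. Membership is half-open:
#' `lat_lo <= lat < lat_hi`.
#'
#' @param id integer identifier.
#' @param lat_lo,lat_hi southern/northern bounds, degrees north.
#' @param label human-readable name.
#' @return An object of class `area_band`.
#' @export
area_band <- function(id, lat_lo, lat_hi, label = paste0("band", id)) {
  if (lat_hi <= lat_lo) stop("area_band: lat_hi must exceed lat_lo")
  structure(list(id = id, lat_lo = lat_lo, lat_hi = lat_hi, label = label),
            class = "area_band")
}

#' @rdname area_band
#' @return `default_area_bands()` returns the list of the five standard bands:
#'   1 `[26,30)`, 2 `[21,26)`, 3 `[20,21)`, 4 `[16,21)`, 5 `[12,16)`.
#' @export
default_area_bands <- function() {
  list(area_band(1L, 26, 30, "North of Cape Boujdour"),
       area_band(2L, 21, 26, "Cape Blanc to Cape Boujdour"),
       area_band(3L, 20, 21, "Around Cape Blanc"),
       area_band(4L, 16, 21, "Mauritania"),
       area_band(5L, 12, 16, "Senegal"))
}

#' Great-circle distance (haversine) in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised and recycled
#' over its arguments. Symmetric, non-negative, zero iff the points coincide.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; latitudes must
#'   be in `[-90, 90]`.
#' @return distance(s) in km.
#' @examples
#' haversine_km(19, -17, 20, -17)  # one degree of meridian: 111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("haversine_km: latitude outside [-90, 90]")
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad / 2
  dlam <- (lon2 - lon1) * rad / 2
  a <- sin(dphi)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Densify a polyline so consecutive vertices are no more than max_step degrees
# apart (in the larger of the lat/lon increments).
densify_polyline <- function(poly, max_step) {
  lat <- poly[, "lat"]; lon <- poly[, "lon"]
  out_lat <- list(); out_lon <- list()
  for (i in seq_len(nrow(poly) - 1L)) {
    n <- max(1L, ceiling(max(abs(lat[i + 1] - lat[i]),
                             abs(lon[i + 1] - lon[i])) / max_step))
    s <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out_lat[[i]] <- lat[i] + s * (lat[i + 1] - lat[i])
    out_lon[[i]] <- lon[i] + s * (lon[i + 1] - lon[i])
  }
  cbind(lat = c(unlist(out_lat), lat[length(lat)]),
        lon = c(unlist(out_lon), lon[length(lon)]))
}

#' Distance-to-coast field and ocean mask
#'
#' For every ocean cell center of `grid`, the minimum great-circle distance to
#' the coastline polyline (densified so that inter-vertex spacing does not
#' exceed the grid resolution). A cell is "ocean" iff its center lies on the
#' ocean side of the coastline at the cell's latitude; land cells carry `NA`
#' distance.
#'
#' @param grid a [grid_spec()].
#' @param coast a [coast_geometry()]; its coastline must span the latitude
#'   range of the grid cell centers.
#' @return list with `distance_km` (`n_lat x n_lon` matrix, `NA` on land),
#'   `ocean` (logical matrix), `lat`, `lon` (cell-center coordinates).
#' @export
distance_to_coast_field <- function(grid, coast) {
  lat <- grid_lat(grid); lon <- grid_lon(grid)
  crng <- range(coast$coastline[, "lat"])
  if (crng[1] > min(lat) || crng[2] < max(lat))
    stop(sprintf(paste0("distance_to_coast_field: coastline latitude range ",
                        "[%g, %g] does not cover grid cell centers [%g, %g]"),
                 crng[1], crng[2], min(lat), max(lat)))
  # spacing well below the grid resolution keeps the point-sampling error of
  # the nearest-distance search under ~0.5 km even close to the coast
  dense <- densify_polyline(coast$coastline, min(grid$resolution, 0.01))
  coast_lon <- polyline_lon_at(coast$coastline, lat)
  ocean <- if (coast$ocean_side == "west") {
    outer(coast_lon, lon, function(cl, l) l < cl)
  } else {
    outer(coast_lon, lon, function(cl, l) l > cl)
  }
  rad <- pi / 180
  plat <- dense[, "lat"]; plon <- dense[, "lon"]
  cos_plat <- cos(plat * rad)
  dist <- matrix(NA_real_, length(lat), length(lon))
  for (i in seq_along(lat)) {
    cols <- which(ocean[i, ])
    if (!length(cols)) next
    dphi <- (plat - lat[i]) * rad / 2
    # n_pts x n_cols haversine between one grid row and all coast points
    sin2 <- outer(sin(dphi)^2,
                  rep(1, length(cols))) +
      (cos(lat[i] * rad) * cos_plat) * sin(outer(plon, lon[cols], "-") * rad / 2)^2
    dist[i, cols] <- 2 * EARTH_RADIUS_KM *
      apply(asin(pmin(sqrt(sin2), 1)), 2, min)
  }
  # cells exactly on the coastline (center on a vertex) count as ocean, dist 0
  list(distance_km = dist, ocean = ocean, lat = lat, lon = lon)
}

#' Coastal-strip mask
#'
#' Boolean field selecting ocean cells within `width_km` of the coastline.
#' `width_km = 0` is the degenerate case selecting only cells at distance 0;
#' negative widths are an error. The mask is monotone in width.
#'
#' @param grid a [grid_spec()].
#' @param coast a [coast_geometry()].
#' @param width_km strip width in km (default 100, the standard coastal strip).
#' @param dist optional precomputed result of [distance_to_coast_field()].
#' @return logical `n_lat x n_lon` matrix.
#' @export
coastal_mask <- function(grid, coast, width_km = 100, dist = NULL) {
  if (width_km < 0) stop("coastal_mask: width_km must be non-negative")
  if (is.null(dist)) dist <- distance_to_coast_field(grid, coast)
  m <- dist$ocean & !is.na(dist$distance_km) & dist$distance_km <= width_km
  m[is.na(m)] <- FALSE
  m
}

#' Local orientation of the 200 m isobath
#'
#' Direction of the isobath tangent pointing poleward, in radians
#' counterclockwise from geographic east, from the finite difference between
#' the two vertices bracketing `lat` in a local-plane approximation (longitude
#' increments scaled by `cos(lat)`). A meridional isobath gives `pi/2`.
#'
#' @param coast a [coast_geometry()].
#' @param lat latitude(s) within the isobath's span, degrees north.
#' @return angle(s) in radians, in `(0, pi)` for a south-to-north polyline.
#' @export
isobath_angle <- function(coast, lat) {
  iso <- coast$isobath200
  lats <- iso[, "lat"]; lons <- iso[, "lon"]
  if (any(lat < lats[1] - 1e-9 | lat > lats[length(lats)] + 1e-9))
    stop(sprintf("isobath_angle: latitude outside isobath span [%g, %g]",
                 lats[1], lats[length(lats)]))
  i <- findInterval(lat, lats, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lats) - 1L)
  dy <- lats[i + 1L] - lats[i]
  dx <- (lons[i + 1L] - lons[i]) * cos(lat * pi / 180)
  atan2(dy, dx)
}

#' Area-averaged monthly series over a masked latitude band
#'
#' Unweighted mean, per month, of the field over cells that are in `mask` and
#' whose center latitude falls in the half-open band `[lat_lo, lat_hi)`. Months
#' where every eligible cell is missing yield `NA`. No cos-latitude weighting
#' is applied: the coastal strip is narrow (see package vignette).
#'
#' @param field a [grid_field()].
#' @param mask logical matrix conforming to the field grid.
#' @param band an [area_band()].
#' @param cos_weight weight cells by cos(latitude) instead of the default
#'   unweighted mean (the strip is narrow; see the methods vignette).
#' @return a [monthly_series()] carrying the field's variable/units and the
#'   band id.
#' @export
area_series <- function(field, mask, band, cos_weight = FALSE) {
  stopifnot(inherits(field, "grid_field"), inherits(band, "area_band"))
  if (!all(dim(mask) == dim(field$data)[1:2]))
    stop("area_series: mask shape does not match field grid")
  in_band <- field$lat >= band$lat_lo & field$lat < band$lat_hi
  sel <- mask & matrix(in_band, nrow = length(field$lat), ncol = length(field$lon))
  if (!any(sel))
    stop("area_series: no eligible cells for band ", band$id,
         " (", band$label, ")")
  idx <- which(sel)
  nt <- dim(field$data)[3]
  flat <- matrix(field$data, ncol = nt)[idx, , drop = FALSE]
  w <- if (cos_weight) {
    cos(matrix(field$lat, length(field$lat), length(field$lon))[idx] * pi / 180)
  } else rep(1, length(idx))
  ok <- !is.na(flat)
  value <- colSums(flat * w, na.rm = TRUE) / colSums(ok * w)
  value[!is.finite(value)] <- NA_real_
  monthly_series(field$time$year, field$time$month, value,
                 variable = field$variable, units = field$units,
                 band = band$id)
}
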