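# Wind stress and the isobath-oriented Ekman upwelling index.

#' Physical constants for the bulk stress / Ekman transport formulas
#'
#' The bulk formula source does not pin numerical constants, so they are fixed
#' here at standard values and are overridable everywhere they are used:
#' air density `rho_air` = 1.22 kg m^-3, drag coefficient `c_drag` = 1.3e-3
#' (dimensionless, wind-speed independent), seawater density `rho_water` =
#' 1025 kg m^-3, Earth rotation rate `omega` = 7.2921e-5 rad s^-1.
#'
#' @param rho_air,c_drag,rho_water,omega overrides; all must be positive.
#' @return a named list of class `physical_constants`.
#' @export
physical_constants <- function(rho_air = 1.22, c_drag = 1.3e-3,
                               rho_water = 1025, omega = 7.2921e-5) {
  vals <- c(rho_air = rho_air, c_drag = c_drag, rho_water = rho_water,
            omega = omega)
  if (any(vals <= 0)) stop("physical_constants: all constants must be positive")
  structure(as.list(vals), class = "physical_constants")
}

#' Wind stress from 10-m wind (bulk formula)
#'
#' `tau = rho_air * C_d * |W| * (u, v)`: stress parallel to the wind with
#' magnitude `rho_air * C_d * |W|^2`. Vectorised.
#'
#' @param u,v 10-m wind components, m s^-1 (east, north).
#' @param constants a [physical_constants()].
#' @return list with components `taux`, `tauy` in N m^-2.
#' @examples
#' wind_stress(10, 0)$taux  # 1.22 * 1.3e-3 * 10 * 10 = 0.1586 N m^-2
#' @export
wind_stress <- function(u, v, constants = physical_constants()) {
  speed <- sqrt(u^2 + v^2)
  k <- constants$rho_air * constants$c_drag * speed
  list(taux = k * u, tauy = k * v)
}

#' Coriolis parameter
#'
#' `f = 2 * omega * sin(lat)`. Latitudes within 5 degrees of the equator are
#' rejected (equatorial singularity of the Ekman balance).
#'
#' @param lat latitude(s), degrees.
#' @param constants a [physical_constants()].
#' @return f in s^-1 (negative in the southern hemisphere).
#' @export
coriolis <- function(lat, constants = physical_constants()) {
  if (any(abs(lat) < 5))
    stop("coriolis: equatorial singularity (|lat| < 5 deg)")
  2 * constants$omega * sin(lat * pi / 180)
}

#' Isobath-oriented Ekman upwelling index
#'
#' Offshore Ekman transport per metre of coast. With the poleward isobath
#' tangent `t = (cos theta, sin theta)` and the offshore normal
#' `n = (-sin theta, cos theta)` (ocean to the left of `t`, the Northwest
#' Africa configuration), the Ekman transport is
#' `M = (tauy / (rho_w f), -taux / (rho_w f))` and the index is `M . n =
#' -(taux cos theta + tauy sin theta) / (rho_w f)`. Positive values mean
#' offshore transport, i.e. upwelling-favourable winds (equatorward alongshore
#' wind on a Northern Hemisphere eastern boundary).
#'
#' @param taux,tauy wind stress components, N m^-2.
#' @param theta isobath tangent angle(s) in radians (see [isobath_angle()]).
#' @param lat latitude(s), degrees; `|lat| >= 5`.
#' @param constants a [physical_constants()].
#' @return index in m^2 s^-1 (per metre of coastline).
#' @examples
#' s <- wind_stress(0, -10)  # 10 m/s equatorward wind
#' ekman_index(s$taux, s$tauy, pi / 2, 21)  # about 2.96 m^2/s, offshore
#' @export
ekman_index <- function(taux, tauy, theta, lat,
                        constants = physical_constants()) {
  f <- coriolis(lat, constants)
  -(taux * cos(theta) + tauy * sin(theta)) / (constants$rho_water * f)
}

#' Upwelling-index field and per-band series
#'
#' Computes the Ekman index cell-wise for every ocean cell in the coastal
#' strip, using the isobath angle at each cell's latitude, then averages into
#' per-band monthly series with [area_series()]. Cell-wise evaluation matters
#' because the bulk stress is quadratic in wind speed: the index of the mean
#' wind is not the mean index.
#'
#' @param u_field,v_field [grid_field()]s of 10-m wind components on a shared
#'   grid.
#' @param coast a [coast_geometry()].
#' @param mask logical coastal-strip matrix (see [coastal_mask()]).
#' @param bands list of [area_band()]s (default [default_area_bands()]
#'   intersected with the grid).
#' @param constants a [physical_constants()].
#' @return list with `field` (index [grid_field()], `NA` outside the mask) and
#'   `series` (named list of [monthly_series()], one per band).
#' @export
ekman_index_field <- function(u_field, v_field, coast, mask,
                              bands = default_area_bands(),
                              constants = physical_constants()) {
  stopifnot(inherits(u_field, "grid_field"), inherits(v_field, "grid_field"))
  if (!identical(dim(u_field$data), dim(v_field$data)))
    stop("ekman_index_field: u and v fields must share the grid and time axis")
  lat <- u_field$lat
  theta <- isobath_angle(coast, lat)
  f <- coriolis(lat, constants)
  nlat <- length(lat); nlon <- length(u_field$lon); nt <- nrow(u_field$time)
  ct <- cos(theta); st <- sin(theta)
  u <- u_field$data; v <- v_field$data
  speed <- sqrt(u^2 + v^2)
  k <- constants$rho_air * constants$c_drag * speed
  # alongshore (poleward) stress component, then index = -tau_along/(rho_w f)
  tau_along <- k * (u * ct + v * st)          # ct/st recycle along lat (dim 1)
  idx <- -tau_along / (constants$rho_water * f)
  idx[array(!mask, dim = c(nlat, nlon, nt))] <- NA_real_
  field <- grid_field(idx, lat, u_field$lon, u_field$time,
                      variable = "upwelling_index", units = "m2 s-1")
  series <- lapply(bands, function(b) area_series(field, mask, b))
  names(series) <- vapply(bands, function(b) paste0("band", b$id), "")
  list(field = field, series = series)
}
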