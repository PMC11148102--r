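# A self-consistent synthetic world: coast geometry, monthly environmental
# fields (SST 1982-2021, wind 1988-2021, two-sensor chlorophyll 1998-2021)
# and annual trawl/acoustic surveys (1995-2006, 2011, 2015), with a recorded
# ground truth for every recoverable parameter.

#' Default species table of the synthetic world
#'
#' Eight small pelagic species with 1995 northern limits (degrees north) and
#' northward drift rates (km per decade) chosen to emulate the magnitudes
#' reported for the southern Canary Current community; the logistic edge
#' occupancy (steepness, detection) is a stand-in model, not an empirical
#' one. NASC parameters are the log-normal station backscatter when present.
#'
#' @return data frame with columns `name`, `limit0`, `drift_km_per_decade`,
#'   `steepness`, `detection`, `nasc_meanlog`, `nasc_sdlog`.
#' @export
default_species <- function() {
  data.frame(
    name = c("S_aur", "S_mad", "C_chr", "D_rho", "B_aur", "S_dor",
             "T_tre", "S_gua"),
    limit0 = c(23.0, 25.0, 18.5, 19.5, 18.5, 18.0, 24.5, 17.8),
    drift_km_per_decade = c(180, 0, 195, 70, 118, 0, 180, 200),
    steepness = 0.3, detection = 0.85,
    nasc_meanlog = 4, nasc_sdlog = 1)
}

#' Synthetic-world configuration
#'
#' All tunable parameters of the synthetic world, with defaults stating the
#' conditions the study describes: a 10--32 degN, -22..-10 degE grid at 0.25
#' degrees (a desk-scale stand-in for 1/24-degree products), SST from 1982,
#' wind from 1988, two-sensor chlorophyll from 1998 (overlap 2003--2010), and
#' 14 November surveys (1995--2006, 2011, 2015) with the 2005 survey truncated
#' at 26.3 degN and no 2011 acoustic biomass.
#'
#' @param seed master integer seed; all component RNG streams are derived
#'   from it (see vignette).
#' @param grid,coast,sst,wind,chl,surveys,fraction named lists overriding
#'   individual defaults (partial lists are merged into the defaults).
#' @param species species table as in [default_species()].
#' @return nested list of class `world_config`.
#' @export
world_config <- function(seed = 1, grid = list(), coast = list(),
                         sst = list(), wind = list(), chl = list(),
                         species = default_species(), surveys = list(),
                         fraction = list()) {
  merge_defaults <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    grid = merge_defaults(list(lat_min = 10, lat_max = 32, lon_min = -22,
                               lon_max = -10, resolution = 0.25), grid),
    coast = merge_defaults(list(lon_base = -15.5, bump_amplitude = 1.5,
                                vertex_spacing = 0.5,
                                isobath_offset_km = 40), coast),
    sst = merge_defaults(list(start_year = 1982, end_year = 2021,
                              mean_at_12n = 27.5, gradient_per_deglat = 0.5,
                              seasonal_amplitude = 2, peak_month = 10,
                              trend_per_decade = 0.3,
                              step_year = NA, step_delta = 0,
                              cooling_max = 3, cooling_efold_km = 60,
                              cooling_peak_month = 3,
                              noise_phi = 0.6, noise_sigma = 0.4), sst),
    wind = merge_defaults(list(start_year = 1988, end_year = 2021,
                               mean_speed = 7, trend_per_decade = 0.2,
                               seasonal_amplitude = 1, peak_month = 2,
                               noise_sigma = 0.5), wind),
    chl = merge_defaults(list(start_year = 1998, end_year = 2021,
                              background = 0.3, enrichment = 4,
                              efold_km = 50, trend_per_decade = 0,
                              log_sigma = 0.25,
                              bias_seawifs = 1, bias_modis = 1.15,
                              span_seawifs = c(1998, 2010),
                              span_modis = c(2003, 2021)), chl),
    species = species,
    surveys = merge_defaults(list(years = c(1995:2006, 2011, 2015),
                                  month = 11, lat_south = 12.3,
                                  transect_spacing = 0.25,
                                  stations_per_transect = 2,
                                  station_offsets_km = c(15, 45),
                                  coverage_default = 30,
                                  coverage_overrides = c("2005" = 26.3),
                                  no_biomass_years = 2011,
                                  total_nasc_meanlog = log(1e5),
                                  total_nasc_sdlog = 0.3), surveys),
    fraction = merge_defaults(list(species = "S_aur", boundary_lat = 21,
                                   f_start = 0.38, f_end = 0.65,
                                   year_start = 1995, year_end = 2015,
                                   logit_sigma = 0.2), fraction))
  # normalise structures that may arrive from JSON configs
  cfg$surveys$coverage_overrides <- unlist(cfg$surveys$coverage_overrides)
  cfg$species <- as.data.frame(cfg$species)
  with(cfg, {
    if (sst$noise_sigma < 0 || wind$noise_sigma < 0 || chl$log_sigma < 0 ||
        fraction$logit_sigma < 0)
      stop("world_config: noise sigmas must be non-negative")
    if (sst$noise_phi <= 0 || sst$noise_phi >= 1)
      stop("world_config: AR(1) phi must be in (0, 1)")
    if (!all(is.finite(species$drift_km_per_decade)))
      stop("world_config: species drift must be finite")
    if (any(surveys$years < 1982 | surveys$years > 2021))
      stop("world_config: survey years must lie in [1982, 2021]")
  })
  structure(cfg, class = "world_config")
}

# One RNG substream seed per component, derived from the master seed, so that
# e.g. adding a species never perturbs the SST noise stream.
derive_substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(2147483646L, 6L)
  names(s) <- c("sst", "wind", "chl", "surveys", "fraction", "species")
  s
}

#' Build the synthetic coast geometry
#'
#' A gently curving coastline (a westward bulge centred mid-domain, echoing
#' the Cape Blanc region) with the 200 m isobath offset a fixed distance
#' offshore (west).
#'
#' @param config a [world_config()].
#' @return a [coast_geometry()].
#' @export
build_coast <- function(config) {
  g <- config$grid; cc <- config$coast
  lat <- seq(g$lat_min, g$lat_max, by = cc$vertex_spacing)
  if (lat[length(lat)] < g$lat_max) lat <- c(lat, g$lat_max)
  lon <- cc$lon_base - cc$bump_amplitude *
    sin(pi * (lat - g$lat_min) / (g$lat_max - g$lat_min))
  iso_lon <- lon - cc$isobath_offset_km / (KM_PER_DEG_LAT * cos(lat * pi / 180))
  coast_geometry(cbind(lat = lat, lon = lon),
                 cbind(lat = lat, lon = iso_lon), ocean_side = "west")
}

# Survey-time true northern limit of each species (degrees north).
true_limits <- function(config, years) {
  sp <- config$species
  outer(years, seq_len(nrow(sp)), function(y, s)
    sp$limit0[s] + sp$drift_km_per_decade[s] / KM_PER_DEG_LAT *
      (y - config$fraction$year_start) / 10) |>
    (\(m) {dimnames(m) <- list(years, sp$name); m})()
}

#' Ground truth of a synthetic world
#'
#' The realized (recoverable) parameters: configured per-band environmental
#' trends (with the upwelling-index trend implied by the quadratic stress
#' law, evaluated at band mid-latitudes), per-species yearly true northern
#' limits, and the realized per-year biomass fraction north of the boundary
#' (logit-linear ramp plus year-level noise, drawn from its own RNG
#' substream). Bit-reproducible from `(config, seed)`.
#'
#' @param config a [world_config()].
#' @param bands list of [area_band()]s for the implied upwelling trend.
#' @return list of class `world_truth`.
#' @export
world_truth <- function(config, bands = default_area_bands()) {
  seeds <- derive_substream_seeds(config$seed)
  sv <- config$surveys; fr <- config$fraction
  limits <- true_limits(config, sv$years)
  # realized fraction ramp with year-level logit noise
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seeds["fraction"])
  l0 <- stats::qlogis(fr$f_start); l1 <- stats::qlogis(fr$f_end)
  lin <- l0 + (l1 - l0) * (sv$years - fr$year_start) /
    (fr$year_end - fr$year_start)
  frac <- stats::plogis(lin + stats::rnorm(length(sv$years), 0, fr$logit_sigma))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  # implied deterministic upwelling-index annual trend per band (quadratic
  # stress law at the band mid-latitude, equatorward alongshore wind)
  w <- config$wind; k <- physical_constants()
  upw_trend <- vapply(bands, function(b) {
    mid <- (b$lat_lo + b$lat_hi) / 2
    yrs <- w$start_year:w$end_year
    s2 <- (w$mean_speed + w$trend_per_decade / 10 *
             (yrs - w$start_year + 0.5))^2 + w$seasonal_amplitude^2 / 2
    idx <- k$rho_air * k$c_drag * s2 / (k$rho_water * coriolis(mid, k))
    linear_trend(yrs, idx)$slope_per_decade
  }, 0.0)
  names(upw_trend) <- vapply(bands, function(b) paste0("band", b$id), "")
  structure(list(
    trends = list(sst_per_decade = config$sst$trend_per_decade,
                  wind_per_decade = config$wind$trend_per_decade,
                  chl_per_decade = config$chl$trend_per_decade,
                  upwelling_per_decade = upw_trend),
    species_drift_km_per_decade = stats::setNames(
      config$species$drift_km_per_decade, config$species$name),
    species_limits = limits,
    fraction_north = data.frame(year = sv$years, fraction = frac),
    seed = config$seed), class = "world_truth")
}

# months table + fractional years since start (month centers)
field_time <- function(start_year, end_year) {
  tm <- month_seq(start_year, end_year)
  tm$t <- (tm$year - start_year) + (tm$month - 0.5) / 12
  tm
}

# stationary AR(1) noise, marginal sd sigma, as ncell x ntime matrix
ar1_noise <- function(ncell, ntime, phi, sigma) {
  if (sigma == 0) return(matrix(0, ncell, ntime))
  z0 <- stats::rnorm(ncell, 0, sigma)
  innov <- matrix(stats::rnorm(ncell * ntime, 0, sigma * sqrt(1 - phi^2)),
                  ntime, ncell)
  x <- rbind(z0, innov)
  y <- stats::filter(x, phi, method = "recursive")
  t(unclass(y)[-1, , drop = FALSE])
}

#' Generate the synthetic SST field
#'
#' `T(cell, month) = T12 - g (lat - 12) + A cos(2 pi (month - peak)/12)
#'  + trend * t + step + cooling + AR(1) noise`, where the coastal upwelling
#' cooling is `-cool_max * exp(-d_coast / L) * s(month)` with seasonal factor
#' `s = (1 + cos(2 pi (month - peak_cool)/12)) / 2`, and the AR(1) noise has
#' marginal standard deviation `noise_sigma`. Land cells are missing.
#'
#' @param config a [world_config()].
#' @param coast a [coast_geometry()] (default [build_coast()]).
#' @param dist optional precomputed [distance_to_coast_field()].
#' @param seed RNG seed for the noise stream (default: the sst substream of
#'   the master seed).
#' @return a [grid_field()] of SST in degC.
#' @export
generate_sst <- function(config, coast = build_coast(config), dist = NULL,
                         seed = derive_substream_seeds(config$seed)["sst"]) {
  g <- do.call(grid_spec, config$grid[c("lat_min", "lat_max", "lon_min",
                                        "lon_max", "resolution")])
  if (is.null(dist)) dist <- distance_to_coast_field(g, coast)
  p <- config$sst
  tm <- field_time(p$start_year, p$end_year)
  nlat <- g$n_lat; nlon <- g$n_lon; nt <- nrow(tm)
  lat_term <- matrix(p$mean_at_12n - p$gradient_per_deglat * (dist$lat - 12),
                     nlat, nlon)
  season <- p$seasonal_amplitude * cos(2 * pi * (tm$month - p$peak_month) / 12)
  trend <- p$trend_per_decade / 10 * tm$t
  step <- if (!is.na(p$step_year)) p$step_delta * (tm$year >= p$step_year) else 0
  cool_space <- p$cooling_max * exp(-dist$distance_km / p$cooling_efold_km)
  cool_space[is.na(cool_space)] <- 0
  cool_season <- (1 + cos(2 * pi * (tm$month - p$cooling_peak_month) / 12)) / 2
  det <- outer(lat_term, season + trend + step, "+") -
    outer(cool_space, cool_season, "*")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  noise <- ar1_noise(nlat * nlon, nt, p$noise_phi, p$noise_sigma)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- det + array(noise, dim = c(nlat, nlon, nt))
  out[array(!dist$ocean, dim = c(nlat, nlon, nt))] <- NA_real_
  grid_field(out, dist$lat, dist$lon, tm[c("year", "month")], "sst", "degC")
}

#' Generate the synthetic 10-m wind fields
#'
#' Equatorward alongshore wind: speed `s = mean + trend * t + A cos(...) +
#' noise` (white, floored at 0), decomposed as `(u, v) = -s (cos theta,
#' sin theta)` from the local isobath tangent angle at each cell's latitude.
#'
#' @inheritParams generate_sst
#' @return list with `u` and `v` [grid_field()]s in m s^-1.
#' @export
generate_wind <- function(config, coast = build_coast(config), dist = NULL,
                          seed = derive_substream_seeds(config$seed)["wind"]) {
  g <- do.call(grid_spec, config$grid[c("lat_min", "lat_max", "lon_min",
                                        "lon_max", "resolution")])
  if (is.null(dist)) dist <- distance_to_coast_field(g, coast)
  p <- config$wind
  tm <- field_time(p$start_year, p$end_year)
  nlat <- g$n_lat; nlon <- g$n_lon; nt <- nrow(tm)
  season <- p$seasonal_amplitude * cos(2 * pi * (tm$month - p$peak_month) / 12)
  base <- p$mean_speed + p$trend_per_decade / 10 * tm$t + season
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  noise <- if (p$noise_sigma > 0)
    array(stats::rnorm(nlat * nlon * nt, 0, p$noise_sigma),
          dim = c(nlat, nlon, nt)) else 0
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  speed <- pmax(outer(matrix(0, nlat, nlon), base, "+") + noise, 0)
  theta <- isobath_angle(coast, dist$lat)
  u <- -speed * cos(theta)   # theta recycles along dim 1 (latitude)
  v <- -speed * sin(theta)
  land <- array(!dist$ocean, dim = c(nlat, nlon, nt))
  u[land] <- NA_real_; v[land] <- NA_real_
  list(u = grid_field(u, dist$lat, dist$lon, tm[c("year", "month")],
                      "wind_u", "m s-1"),
       v = grid_field(v, dist$lat, dist$lon, tm[c("year", "month")],
                      "wind_v", "m s-1"))
}

#' Generate the two synthetic chlorophyll sensor fields
#'
#' True chlorophyll is `background + trend * t + enrichment * s(month) *
#' exp(-d_coast / L)` with `s` the normalized (0--1) seasonal upwelling
#' proxy. Each sensor observes `truth * bias * exp(sigma Z)` (independent
#' log-normal noise) over its own span and is missing outside it; all values
#' are positive.
#'
#' @inheritParams generate_sst
#' @return list with `seawifs` and `modis` [grid_field()]s in mg m^-3.
#' @export
generate_chl <- function(config, coast = build_coast(config), dist = NULL,
                         seed = derive_substream_seeds(config$seed)["chl"]) {
  g <- do.call(grid_spec, config$grid[c("lat_min", "lat_max", "lon_min",
                                        "lon_max", "resolution")])
  if (is.null(dist)) dist <- distance_to_coast_field(g, coast)
  p <- config$chl
  tm <- field_time(p$start_year, p$end_year)
  nlat <- g$n_lat; nlon <- g$n_lon; nt <- nrow(tm)
  proxy <- (1 + cos(2 * pi * (tm$month - config$sst$cooling_peak_month) / 12)) / 2
  enrich <- p$enrichment * exp(-dist$distance_km / p$efold_km)
  enrich[is.na(enrich)] <- 0
  truth <- outer(matrix(0, nlat, nlon),
                 p$background + p$trend_per_decade / 10 * tm$t, "+") +
    outer(enrich, proxy, "*")
  mask_span <- function(out, span) {
    bad <- which(tm$year < span[1] | tm$year > span[2])
    if (length(bad)) out[, , bad] <- NA_real_
    out
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  mk <- function(bias, span) {
    z <- if (p$log_sigma > 0)
      array(stats::rnorm(nlat * nlon * nt, 0, p$log_sigma),
            dim = c(nlat, nlon, nt)) else array(0, dim = c(nlat, nlon, nt))
    mask_span(truth * bias * exp(z), span)
  }
  a <- mk(p$bias_seawifs, p$span_seawifs)
  b <- mk(p$bias_modis, p$span_modis)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  land <- array(!dist$ocean, dim = c(nlat, nlon, nt))
  a[land] <- NA_real_; b[land] <- NA_real_
  list(seawifs = grid_field(a, dist$lat, dist$lon, tm[c("year", "month")],
                            "chl_seawifs", "mg m-3"),
       modis = grid_field(b, dist$lat, dist$lon, tm[c("year", "month")],
                          "chl_modis", "mg m-3"))
}

#' Generate synthetic trawl and acoustic surveys
#'
#' Stations are placed on transects every `transect_spacing` degrees of
#' latitude from `lat_south` up to the year's coverage limit, at fixed
#' offshore offsets from the coast. Species presence at a station is
#' Bernoulli with `p = detection * plogis((L_s(year) - lat) / steepness)`
#' (`steepness = 0` is the step-function limit: present iff `lat <
#' L_s(year)`), and station NASC is log-normal when present. Acoustic bins
#' aggregate NASC by 0.5-degree half-open latitude bins; for the focal
#' species the north/south split about the boundary is rescaled to the
#' realized truth fraction. Years in `no_biomass_years` get no acoustic
#' bins and `has_biomass = FALSE`.
#'
#' @param config a [world_config()].
#' @param truth a [world_truth()] (regenerated if omitted).
#' @param coast a [coast_geometry()] (default [build_coast()]).
#' @param seed RNG seed (default: the surveys substream).
#' @return list with `trawls` (wide data frame), `acoustic` (long bins data
#'   frame: year, species, bin_lo, bin_hi, nasc) and `meta`
#'   ([survey_meta()]).
#' @export
generate_surveys <- function(config, truth = world_truth(config),
                             coast = build_coast(config),
                             seed = derive_substream_seeds(config$seed)["surveys"]) {
  sv <- config$surveys; sp <- config$species
  coverage <- rep(sv$coverage_default, length(sv$years))
  ov <- sv$coverage_overrides
  if (length(ov)) {
    m <- match(as.integer(names(ov)), sv$years)
    coverage[m[!is.na(m)]] <- ov[!is.na(m)]
  }
  if (any(coverage <= sv$lat_south))
    stop("generate_surveys: coverage limit south of all transects")
  offsets <- sv$station_offsets_km[seq_len(sv$stations_per_transect)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  species_seeds <- sample.int(2147483646L, nrow(sp) + 2L)
  trawls <- list(); acoustic <- list()
  for (yi in seq_along(sv$years)) {
    y <- sv$years[yi]
    tlat <- seq(sv$lat_south, coverage[yi], by = sv$transect_spacing)
    lat <- rep(tlat, each = length(offsets))
    clon <- polyline_lon_at(coast$coastline, lat)
    lon <- clon - rep(offsets, length(tlat)) /
      (KM_PER_DEG_LAT * cos(lat * pi / 180))
    day <- 1L + (seq_along(lat) - 1L) %/%
      max(1L, ceiling(length(lat) / 28))
    rec <- data.frame(year = y,
                      date = sprintf("%d-%02d-%02d", y, sv$month,
                                     pmin(day, 28L)),
                      lat = lat, lon = lon)
    for (s in seq_len(nrow(sp))) {
      set.seed((as.numeric(species_seeds[s]) + 7919 * yi) %% 2147483647)
      p <- if (sp$steepness[s] == 0) {
        sp$detection[s] * as.numeric(lat < truth$species_limits[yi, s])
      } else {
        sp$detection[s] *
          stats::plogis((truth$species_limits[yi, s] - lat) / sp$steepness[s])
      }
      pres <- stats::runif(length(lat)) < p
      catch <- numeric(length(lat))
      catch[pres] <- stats::rlnorm(sum(pres), sp$nasc_meanlog[s],
                                   sp$nasc_sdlog[s])
      rec[[sp$name[s]]] <- catch
    }
    trawls[[yi]] <- rec
    if (!(y %in% sv$no_biomass_years)) {
      set.seed((as.numeric(species_seeds[nrow(sp) + 1L]) + 7919 * yi) %% 2147483647)
      total <- stats::rlnorm(1, sv$total_nasc_meanlog, sv$total_nasc_sdlog)
      for (s in seq_len(nrow(sp))) {
        nasc <- rec[[sp$name[s]]]
        if (sp$name[s] == config$fraction$species) {
          fy <- truth$fraction_north$fraction[truth$fraction_north$year == y]
          north <- lat >= config$fraction$boundary_lat
          sn <- sum(nasc[north]); ss <- sum(nasc[!north])
          if (sn > 0 && ss > 0 && length(fy) == 1) {
            nasc[north] <- nasc[north] / sn * fy * total
            nasc[!north] <- nasc[!north] / ss * (1 - fy) * total
          }
        }
        keep <- nasc > 0
        if (!any(keep)) next
        bin_lo <- floor(lat[keep] * 2) / 2
        agg <- stats::aggregate(list(nasc = nasc[keep]),
                                by = list(bin_lo = bin_lo), FUN = sum)
        acoustic[[length(acoustic) + 1L]] <-
          data.frame(year = y, species = sp$name[s], bin_lo = agg$bin_lo,
                     bin_hi = agg$bin_lo + 0.5, nasc = agg$nasc)
      }
    }
  }
  list(trawls = do.call(rbind, trawls),
       acoustic = if (length(acoustic)) do.call(rbind, acoustic) else
         data.frame(year = integer(), species = character(),
                    bin_lo = numeric(), bin_hi = numeric(), nasc = numeric()),
       meta = survey_meta(sv$years, coverage,
                          !(sv$years %in% sv$no_biomass_years)))
}

#' Build the full synthetic world
#'
#' Orchestrates coast, truth, all environmental fields and the surveys.
#' Deterministic given the config seed.
#'
#' @param config a [world_config()].
#' @param components character subset of
#'   `c("sst", "wind", "chl", "surveys")` to generate (all by default).
#' @return list of class `world` with `config`, `coast`, `dist`, `truth`,
#'   and the requested components (`sst`, `wind` (list u, v), `chl` (list
#'   seawifs, modis), `surveys` (list trawls, acoustic, meta)).
#' @export
build_world <- function(config = world_config(),
                        components = c("sst", "wind", "chl", "surveys")) {
  stopifnot(inherits(config, "world_config"))
  components <- match.arg(components, several.ok = TRUE)
  g <- do.call(grid_spec, config$grid[c("lat_min", "lat_max", "lon_min",
                                        "lon_max", "resolution")])
  coast <- build_coast(config)
  dist <- distance_to_coast_field(g, coast)
  truth <- world_truth(config)
  seeds <- derive_substream_seeds(config$seed)
  out <- list(config = config, grid = g, coast = coast, dist = dist,
              truth = truth)
  if ("sst" %in% components)
    out$sst <- generate_sst(config, coast, dist, seeds["sst"])
  if ("wind" %in% components)
    out$wind <- generate_wind(config, coast, dist, seeds["wind"])
  if ("chl" %in% components)
    out$chl <- generate_chl(config, coast, dist, seeds["chl"])
  if ("surveys" %in% components)
    out$surveys <- generate_surveys(config, truth, coast, seeds["surveys"])
  structure(out, class = "world")
}
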