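# Shared fixtures: all built in code, no files.

# straight meridional coast at lon = coast_lon, isobath offset west
meridional_coast <- function(lat_lo = 10, lat_hi = 32, coast_lon = -16,
                             iso_offset = 0.5) {
  lat <- seq(lat_lo, lat_hi, by = 1)
  coast_geometry(cbind(lat = lat, lon = rep(coast_lon, length(lat))),
                 cbind(lat = lat, lon = rep(coast_lon - iso_offset, length(lat))))
}

# grid_field built from f(lat, lon, year, month)
field_from_fun <- function(f, lat, lon, years, variable = "sst",
                           units = "degC") {
  tm <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  data <- array(NA_real_, c(length(lat), length(lon), nrow(tm)))
  ll <- expand.grid(lat = lat, lon = lon)
  for (k in seq_len(nrow(tm)))
    data[, , k] <- rep_len(f(ll$lat, ll$lon, tm$year[k], tm$month[k]),
                           nrow(ll))
  grid_field(data, lat, lon, tm, variable, units)
}

# a small synthetic world config that runs in well under a second;
# named overrides replace the corresponding default argument wholesale
small_world_config <- function(seed = 3, ...) {
  args <- list(
    seed = seed,
    grid = list(lat_min = 16, lat_max = 24, lon_min = -20, lon_max = -14,
                resolution = 0.5),
    sst = list(start_year = 1998, end_year = 2009),
    wind = list(start_year = 1998, end_year = 2009),
    chl = list(start_year = 1998, end_year = 2009,
               span_seawifs = c(1998, 2006), span_modis = c(2003, 2009)),
    species = transform(default_species(),
                        limit0 = pmin(pmax(limit0, 17), 22)),
    fraction = list(year_start = 2000, year_end = 2006),
    surveys = list(years = 2000:2006, lat_south = 16.3,
                   coverage_default = 23.5,
                   coverage_overrides = c("2005" = 21),
                   no_biomass_years = 2004))
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(world_config, args)
}

# hand-rolled limit series for bootstrap tests
make_limits <- function(year, limit, censored = FALSE, species = "sp") {
  structure(data.frame(year = year, limit = limit,
                       censored = rep_len(censored, length(year))),
            species = species, class = c("limit_series", "data.frame"))
}
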