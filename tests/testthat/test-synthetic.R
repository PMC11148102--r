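test_that("world_config validates invariants", {
  expect_error(world_config(sst = list(noise_sigma = -1)), "sigma")
  expect_error(world_config(sst = list(noise_phi = 1.2)), "phi")
  expect_error(world_config(surveys = list(years = c(1970, 2000))),
               "survey years")
  sp <- default_species(); sp$drift_km_per_decade[1] <- Inf
  expect_error(world_config(species = sp), "finite")
  expect_error(world_config(sst = list(nonexistent_knob = 1)), "names")
})

test_that("build_world is deterministic under a fixed seed", {
  cfg <- small_world_config(seed = 21)
  w1 <- build_world(cfg)
  w2 <- build_world(cfg)
  expect_identical(w1$sst$data, w2$sst$data)
  expect_identical(w1$wind$u$data, w2$wind$u$data)
  expect_identical(w1$chl$modis$data, w2$chl$modis$data)
  expect_identical(w1$surveys$trawls, w2$surveys$trawls)
  expect_identical(w1$surveys$acoustic, w2$surveys$acoustic)
  expect_identical(w1$truth$fraction_north, w2$truth$fraction_north)
  # different seed, different noise
  w3 <- build_world(small_world_config(seed = 22))
  expect_false(identical(w1$sst$data, w3$sst$data))
})

test_that("adding a species does not perturb field noise or other species", {
  cfg <- small_world_config(seed = 21)
  sp2 <- rbind(cfg$species,
               data.frame(name = "X_new", limit0 = 19,
                          drift_km_per_decade = 50, steepness = 0.3,
                          detection = 0.8, nasc_meanlog = 3, nasc_sdlog = 1))
  cfg2 <- small_world_config(seed = 21, species = sp2)
  w1 <- build_world(cfg); w2 <- build_world(cfg2)
  expect_identical(w1$sst$data, w2$sst$data)
  expect_identical(w1$surveys$trawls$S_aur, w2$surveys$trawls$S_aur)
  expect_identical(w1$surveys$trawls$S_gua, w2$surveys$trawls$S_gua)
  expect_true("X_new" %in% names(w2$surveys$trawls))
})

test_that("noise-free SST reproduces its closed-form formula exactly", {
  # part 1: cooling off -> clean closed form T = T12 - g (lat-12) + A + trend
  cfg <- small_world_config(
    seed = 2, sst = list(start_year = 2000, end_year = 2004,
                         noise_sigma = 0, cooling_max = 0))
  w <- build_world(cfg, components = "sst")
  p <- cfg$sst
  tm <- w$sst$time
  ocean <- which(w$dist$ocean, arr.ind = TRUE)
  i <- ocean[1, 1]; j <- ocean[1, 2]
  k <- which(tm$month == p$peak_month)[3]
  t_frac <- (tm$year[k] - p$start_year) + (tm$month[k] - 0.5) / 12
  expect_equal(w$sst$data[i, j, k],
               p$mean_at_12n - p$gradient_per_deglat * (w$dist$lat[i] - 12) +
                 p$seasonal_amplitude + p$trend_per_decade / 10 * t_frac,
               tolerance = 1e-10)
  # part 2: cooling on; same latitude, coastal vs offshore cells differ by
  # exactly the exponential cooling difference (all other terms cancel)
  cfg2 <- small_world_config(
    seed = 2, sst = list(start_year = 2000, end_year = 2004,
                         noise_sigma = 0))
  w2 <- build_world(cfg2, components = "sst")
  p2 <- cfg2$sst
  row <- which(rowSums(w2$dist$ocean) >= 4)[3]
  ocean_cols <- which(w2$dist$ocean[row, ])
  jc <- ocean_cols[which.max(w2$dist$distance_km[row, ocean_cols] * -1)]
  jf <- ocean_cols[which.max(w2$dist$distance_km[row, ocean_cols])]
  k2 <- which(w2$sst$time$month == p2$cooling_peak_month)[1]
  dT <- w2$sst$data[row, jf, k2] - w2$sst$data[row, jc, k2]
  expect_equal(dT, p2$cooling_max *
                 (exp(-w2$dist$distance_km[row, jc] / p2$cooling_efold_km) -
                    exp(-w2$dist$distance_km[row, jf] / p2$cooling_efold_km)),
               tolerance = 1e-10)
})

test_that("noise-free band series recover the configured trend exactly", {
  cfg <- small_world_config(seed = 2)
  cfg$sst$noise_sigma <- 0
  w <- build_world(cfg, components = "sst")
  mask <- coastal_mask(w$grid, w$coast, 100, w$dist)
  s <- area_series(w$sst, mask, area_band(4L, 16, 21))
  tr <- linear_trend(annual_mean(s))
  expect_equal(tr$slope_per_decade, cfg$sst$trend_per_decade,
               tolerance = 1e-10)
  expect_equal(abs(tr$pearson_r), 1, tolerance = 1e-9)
  # optional step change shifts the post-step years bodily
  cfg2 <- small_world_config(seed = 2)
  cfg2$sst$noise_sigma <- 0; cfg2$sst$trend_per_decade <- 0
  cfg2$sst$step_year <- 2004; cfg2$sst$step_delta <- 0.7
  w2 <- build_world(cfg2, components = "sst")
  s2 <- area_series(w2$sst, mask, area_band(4L, 16, 21))
  ann <- annual_mean(s2)
  expect_equal(mean(ann$value[ann$year >= 2004]) -
                 mean(ann$value[ann$year < 2004]), 0.7, tolerance = 1e-10)
})

test_that("noise-free wind speed matches the configured series at the coast", {
  cfg <- small_world_config(seed = 2)
  cfg$wind$noise_sigma <- 0
  w <- build_world(cfg, components = "wind")
  sp <- sqrt(w$wind$u$data^2 + w$wind$v$data^2)
  p <- cfg$wind
  tm <- w$wind$u$time
  expected <- p$mean_speed + p$trend_per_decade / 10 *
    ((tm$year - p$start_year) + (tm$month - 0.5) / 12) +
    p$seasonal_amplitude * cos(2 * pi * (tm$month - p$peak_month) / 12)
  ocean <- which(w$dist$ocean, arr.ind = TRUE)
  i <- ocean[5, 1]; j <- ocean[5, 2]
  expect_equal(sp[i, j, ], expected, tolerance = 1e-9)
  # wind points equatorward along the isobath
  expect_true(all(w$wind$v$data < 0, na.rm = TRUE))
  # trend recovery exact in the noise-free limit
  mask <- coastal_mask(w$grid, w$coast, 100, w$dist)
  sf <- grid_field(sp, w$wind$u$lat, w$wind$u$lon, tm, "speed", "m s-1")
  tr <- linear_trend(annual_mean(area_series(sf, mask, area_band(4L, 16, 21))))
  expect_equal(tr$slope_per_decade, p$trend_per_decade, tolerance = 1e-10)
})

test_that("AR(1) noise has the stated long-run behaviour", {
  cfg <- small_world_config(seed = 31)
  cfg$sst$trend_per_decade <- 0
  w <- build_world(cfg, components = "sst")
  det_cfg <- cfg; det_cfg$sst$noise_sigma <- 0
  wd <- build_world(det_cfg, components = "sst")
  noise <- w$sst$data - wd$sst$data
  ocean <- which(w$dist$ocean, arr.ind = TRUE)
  phi <- cfg$sst$noise_phi; sigma <- cfg$sst$noise_sigma
  n <- dim(noise)[3]
  for (r in c(3, 17, 40)) {
    z <- noise[ocean[r, 1], ocean[r, 2], ]
    # long-run mean within 3 standard errors of 0 (AR(1) effective n)
    se <- sigma * sqrt((1 + phi) / (1 - phi) / n)
    expect_lt(abs(mean(z)), 3 * se)
    # marginal sd and lag-1 autocorrelation near their targets
    expect_lt(abs(sd(z) - sigma), 0.35 * sigma)
    expect_lt(abs(cor(z[-1], z[-n]) - phi), 0.2)
  }
})

test_that("band-trend estimates center on the configured trend (200 worlds)", {
  # scaled-down replicate worlds: one band strip, short series, default noise
  est <- vapply(1:200, function(s) {
    cfg <- world_config(
      seed = s,
      grid = list(lat_min = 16, lat_max = 21, lon_min = -20, lon_max = -15,
                  resolution = 0.5),
      sst = list(start_year = 1988, end_year = 2021),
      surveys = list(years = 2000:2006, lat_south = 16.3,
                     coverage_default = 20.5, coverage_overrides = NULL,
                     no_biomass_years = integer()))
    w <- build_world(cfg, components = "sst")
    mask <- coastal_mask(w$grid, w$coast, 100, w$dist)
    s4 <- area_series(w$sst, mask, area_band(4L, 16, 21))
    linear_trend(annual_mean(s4))$slope_per_decade
  }, 0.0)
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("surveys: occupancy edge, NASC positivity, truth bookkeeping", {
  cfg <- small_world_config(seed = 12)
  w <- build_world(cfg, components = "surveys")
  tr <- w$surveys$trawls
  expect_true(all(tr$lat <= 23.5 + 1e-9))
  expect_true(all(tr$lat[tr$year == 2005] <= 21 + 1e-9))
  expect_true(all(vapply(cfg$species$name, function(s) all(tr[[s]] >= 0),
                         TRUE)))
  expect_true(all(w$surveys$acoustic$nasc > 0))
  # realized fractions recorded in truth match the acoustic bins for the
  # focal species
  bins <- w$surveys$acoustic
  fr <- fraction_north(bins[bins$species == "S_aur", ],
                       cfg$fraction$boundary_lat)
  m <- merge(fr, w$truth$fraction_north, by = "year")
  # 2005 coverage stops at the boundary itself: the survey cannot see the
  # northern region, so its raw fraction is 0, not the truth -- excluded here
  m <- m[m$year != 2005, ]
  expect_equal(m$fraction.x, m$fraction.y, tolerance = 1e-9)
  # true limits drift linearly at the configured rate
  lims <- w$truth$species_limits
  drift_deg <- unname(diff(lims[c(1, 7), "S_aur"]))
  expect_equal(drift_deg,
               180 / (pi * 6371 / 180) * 0.6, tolerance = 1e-9)
})
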