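trawl_row <- function(year, lat, catch, species = "S_aur") {
  out <- data.frame(year = year, date = sprintf("%d-11-10", year),
                    lat = lat, lon = -17)
  out[[species]] <- catch
  out
}

test_that("northern_limit: max presence latitude, censoring, monotonicity", {
  meta <- survey_meta(c(2000, 2005), c(26.3, 26.3))
  tr <- rbind(trawl_row(2000, 18.0, 5), trawl_row(2000, 17.0, 2),
              trawl_row(2000, 19.0, 0))
  nl <- northern_limit(tr, "S_aur", 2000, meta)
  expect_equal(nl$limit, 18.0)
  expect_false(nl$censored)
  # presence at the 2005 coverage edge -> censored
  tr2 <- rbind(tr, trawl_row(2005, 26.3, 1))
  nl2 <- northern_limit(tr2, "S_aur", 2005, meta)
  expect_equal(nl2$limit, 26.3)
  expect_true(nl2$censored)
  # absent all year -> missing; no trawls -> error
  tr3 <- trawl_row(2000, 18, 0)
  expect_true(is.na(northern_limit(tr3, "S_aur", 2000, meta)$limit))
  expect_error(northern_limit(tr, "S_aur", 2001, meta), "no trawls")
  expect_error(northern_limit(tr, "nope", 2000, meta), "species")
  # adding a presence record can never decrease the limit
  set.seed(6)
  base <- trawl_row(2000, runif(30, 12, 25), rbinom(30, 1, 0.5) * runif(30))
  l0 <- northern_limit(base, "S_aur", 2000, meta)$limit
  for (k in 1:20) {
    l1 <- northern_limit(rbind(base, trawl_row(2000, runif(1, 12, 26), 1)),
                         "S_aur", 2000, meta)$limit
    expect_gte(l1, l0)
  }
})

test_that("period_shift arithmetic, antisymmetry and censoring exclusion", {
  # A limits {19,19,19} (mean year 1998), B {20,20,20} (mean year 2008):
  # +1 deg over 10 yr -> 111.195 km/decade
  lim <- make_limits(c(1997, 1998, 1999, 2007, 2008, 2009),
                     c(19, 19, 19, 20, 20, 20))
  ps <- period_shift(lim, 1997:1999, 2007:2009)
  expect_equal(ps$shift_km_per_decade, pi * 6371 / 180, tolerance = 1e-9)
  expect_equal(round(ps$shift_km_per_decade, 1), 111.2)
  # A == B -> 0
  lim0 <- make_limits(c(1997:1999, 2007:2009), rep(19, 6))
  expect_equal(period_shift(lim0, 1997:1999, 2007:2009)$shift_km_per_decade, 0)
  # swapping periods flips the sign (per-decade uses |dt| via later period B)
  expect_error(period_shift(lim, 2007:2009, 1997:1999), "later")
  # censored years excluded by default, kept on request
  limc <- make_limits(c(1997, 1998, 1999, 2007, 2008, 2009),
                      c(19, 19, 25, 20, 20, 20),
                      censored = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  psc <- period_shift(limc, 1997:1999, 2007:2009)
  expect_equal(psc$mean_limit_A, 19)
  psk <- period_shift(limc, 1997:1999, 2007:2009, exclude_censored = FALSE)
  expect_equal(psk$mean_limit_A, 21)
  expect_error(period_shift(make_limits(c(1998, 2008), c(19, 20)),
                            1998, 2008), "at least 2")
})

test_that("antisymmetry of the raw latitude difference under period swap", {
  lim <- make_limits(c(1995:1999, 2005:2009),
                     c(18.2, 18.5, 18.1, 18.9, 18.4, 19.6, 19.2, 19.8, 19.5,
                       19.9))
  fwd <- period_shift(lim, 1995:1999, 2005:2009)
  expect_equal(fwd$delta_lat,
               mean(c(19.6, 19.2, 19.8, 19.5, 19.9)) -
                 mean(c(18.2, 18.5, 18.1, 18.9, 18.4)), tolerance = 1e-12)
})

test_that("bootstrap_shift: degenerate cases, determinism, order invariance", {
  n_boot <- 1000
  # A == B element-wise: every delta* = 0 -> p capped at 1
  lim0 <- make_limits(c(1996:1998, 2006:2008), rep(19, 6))
  bs0 <- bootstrap_shift(lim0, 1996:1998, 2006:2008, n_boot = n_boot,
                         seed = 2)
  expect_equal(bs0$p_value, 1)
  expect_equal(unname(bs0$ci), c(0, 0))
  # disjoint degenerate periods: every delta* identical, p = 2/n_boot
  limd <- make_limits(c(1996, 1997, 2006, 2007), c(19, 19, 20, 20))
  bsd <- bootstrap_shift(limd, 1996:1997, 2006:2007, n_boot = n_boot,
                         seed = 2)
  expect_equal(bsd$p_value, 2 / n_boot)
  expect_equal(unname(bsd$ci), rep(bsd$shift_km_per_decade, 2),
               tolerance = 1e-12)
  # deterministic given seed; invariant to record order
  lim <- make_limits(c(1995:1999, 2005:2009),
                     c(18.2, 18.5, 18.1, 18.9, 18.4, 19.6, 19.2, 19.8, 19.5,
                       19.9))
  b1 <- bootstrap_shift(lim, 1995:1999, 2005:2009, n_boot = n_boot, seed = 7)
  b2 <- bootstrap_shift(lim, 1995:1999, 2005:2009, n_boot = n_boot, seed = 7)
  expect_identical(b1[c("ci", "p_value", "shift_km_per_decade")],
                   b2[c("ci", "p_value", "shift_km_per_decade")])
  shuffled <- lim[sample(nrow(lim)), ]
  attr(shuffled, "species") <- "sp"
  class(shuffled) <- class(lim)
  b3 <- bootstrap_shift(shuffled, 1995:1999, 2005:2009, n_boot = n_boot,
                        seed = 7)
  expect_identical(b1[c("ci", "p_value")], b3[c("ci", "p_value")])
  # CI contains the point estimate
  expect_true(b1$ci[1] <= b1$shift_km_per_decade &&
                b1$shift_km_per_decade <= b1$ci[2])
})

test_that("limit_trend converts an exact drift to km per decade", {
  yrs <- 1995:2005
  lim <- make_limits(yrs, 18 + 0.1 * (yrs - 1995))  # 0.1 deg/yr
  tr <- limit_trend(lim)
  expect_equal(tr$slope_per_decade, pi * 6371 / 180, tolerance = 1e-9)
  expect_equal(round(tr$slope_per_decade, 1), 111.2)
  expect_equal(abs(tr$pearson_r), 1)
  lim0 <- make_limits(yrs, rep(18, 11))
  expect_equal(limit_trend(lim0)$slope_per_decade, 0)
  # matches the OLS oracle on 6 hand points
  y6 <- c(18.1, 18.0, 18.4, 18.3, 18.6, 18.9)
  o <- lm(y6 * pi * 6371 / 180 ~ I(1995:2000))
  expect_equal(limit_trend(make_limits(1995:2000, y6))$slope_per_decade,
               10 * unname(coef(o)[2]), tolerance = 1e-9)
})

test_that("hovmoller: aggregation oracle, conservation, missing years", {
  set.seed(9)
  recs <- data.frame(year = sample(c(2000, 2001, 2003), 20, replace = TRUE),
                     bin_lo = sample(seq(14, 20, 0.5), 20, replace = TRUE))
  recs$bin_hi <- recs$bin_lo + 0.5
  recs$nasc <- rlnorm(20, 3, 1)
  meta <- survey_meta(2000:2003, 26, has_biomass = c(TRUE, TRUE, FALSE, TRUE))
  m <- hovmoller(recs, meta)
  # direct aggregation oracle
  for (k in seq_len(nrow(recs))) {
    expect_equal(m[as.character(recs$bin_lo[k]), as.character(recs$year[k])],
                 sum(recs$nasc[recs$bin_lo == recs$bin_lo[k] &
                                 recs$year == recs$year[k]]))
  }
  # column sums equal per-year totals (conservation)
  for (y in c(2000, 2001, 2003))
    expect_equal(sum(m[, as.character(y)]), sum(recs$nasc[recs$year == y]))
  # no-biomass year present as an all-missing column
  expect_true(all(is.na(m[, "2002"])))
  # single-bin world
  one <- data.frame(year = 2000, bin_lo = 18, bin_hi = 18.5, nasc = 4)
  m1 <- hovmoller(one)
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(m1[1, 1], 4)
})

test_that("fraction_north: boundary arithmetic and conservation", {
  bins <- data.frame(year = 2000,
                     bin_lo = c(19, 20, 21, 21.5), bin_hi = c(19.5, 20.5,
                                                              21.5, 22),
                     nasc = c(10, 30, 25, 35))
  fr <- fraction_north(bins, 21)
  expect_equal(fr$fraction, 60 / 100)  # hand computation on the 4-bin toy
  # complement sums to one
  south <- sum(bins$nasc[bins$bin_lo < 21]) / sum(bins$nasc)
  expect_equal(fr$fraction + south, 1)
  # all north / all south / zero total
  expect_equal(fraction_north(transform(bins, bin_lo = bin_lo + 10))$fraction,
               1)
  expect_equal(fraction_north(transform(bins, bin_lo = bin_lo - 10))$fraction,
               0)
  expect_true(is.na(fraction_north(transform(bins, nasc = 0))$fraction))
})

test_that("bootstrap_fraction mirrors the shift bootstrap contract", {
  fr_same <- data.frame(year = c(1995:1997, 2005:2007), fraction = rep(0.4, 6))
  expect_equal(bootstrap_fraction(fr_same, 1995:1997, 2005:2007,
                                  n_boot = 500, seed = 3)$p_value, 1)
  fr_disj <- data.frame(year = c(1995, 1996, 2005, 2006),
                        fraction = c(0.3, 0.3, 0.7, 0.7))
  bt <- bootstrap_fraction(fr_disj, 1995:1996, 2005:2006, n_boot = 500,
                           seed = 3)
  expect_equal(bt$p_value, 2 / 500)
  expect_equal(bt$delta, 0.4)
  expect_error(bootstrap_fraction(fr_disj[1:3, ], 1995:1996, 2005:2006),
               "2 usable")
})

test_that("synthetic surveys: step-function limits, censoring metadata", {
  sp <- data.frame(name = "S_aur", limit0 = 20.4, drift_km_per_decade = 0,
                   steepness = 0, detection = 1, nasc_meanlog = 4,
                   nasc_sdlog = 1)
  cfg <- small_world_config(seed = 5, species = sp,
                            fraction = list(species = "S_aur",
                                            year_start = 2000,
                                            year_end = 2006))
  srv <- generate_surveys(cfg)
  lim <- northern_limit_series(srv$trawls, "S_aur", srv$meta,
                               spacing = cfg$surveys$transect_spacing)
  # step occupancy + full detection: limit = northernmost transect < L
  transects <- seq(16.3, 23.5, by = 0.25)
  expected <- max(transects[transects < 20.4])
  expect_true(all(lim$limit[lim$year != 2005] == expected))
  # 2005 coverage 21 -> same limit, not censored (well south of coverage)
  expect_false(lim$censored[lim$year == 2005])
  # metadata: coverage override and no-biomass flag
  expect_equal(srv$meta$coverage_north_limit[srv$meta$year == 2005], 21)
  expect_identical(srv$meta$has_biomass, srv$meta$year != 2004)
  expect_false(2004 %in% srv$acoustic$year)
})

test_that("censoring triggers when the limit reaches survey coverage", {
  sp <- data.frame(name = "S_aur", limit0 = 23.4, drift_km_per_decade = 0,
                   steepness = 0, detection = 1, nasc_meanlog = 4,
                   nasc_sdlog = 1)
  cfg <- small_world_config(seed = 5, species = sp,
                            surveys = list(years = 2000:2006,
                                           lat_south = 16.3,
                                           coverage_default = 23.5,
                                           coverage_overrides = c("2005" = 21),
                                           no_biomass_years = 2004),
                            fraction = list(species = "S_aur",
                                            year_start = 2000,
                                            year_end = 2006))
  srv <- generate_surveys(cfg)
  lim <- northern_limit_series(srv$trawls, "S_aur", srv$meta, spacing = 0.25)
  # limit 23.3 within one spacing of coverage 23.5 -> censored
  expect_true(all(lim$censored[lim$year != 2005]))
  # 2005 truncated at 21: limit at the 20.8 transect, censored there too
  expect_equal(lim$limit[lim$year == 2005], 20.8)
  expect_true(lim$censored[lim$year == 2005])
})
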