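# Species northern range limits from trawl records, two-period shift with
# bootstrap inference, yearly limit trends, and latitudinal partitioning of
# acoustic biomass.

#' Survey metadata table
#'
#' One row per survey year: northern coverage limit of the survey and whether
#' an acoustic biomass estimate exists for that year.
#'
#' @param year integer survey years (unique).
#' @param coverage_north_limit northernmost surveyed latitude, degrees north.
#' @param has_biomass logical; `FALSE` for years whose acoustic biomass was
#'   not computed (wide transect spacing).
#' @return data frame of class `survey_meta`.
#' @export
survey_meta <- function(year, coverage_north_limit, has_biomass = TRUE) {
  if (anyDuplicated(year)) stop("survey_meta: one record per survey year")
  structure(data.frame(year = as.integer(year),
                       coverage_north_limit = coverage_north_limit,
                       has_biomass = rep_len(has_biomass, length(year))),
            class = c("survey_meta", "data.frame"))
}

#' Annual northern range limit of a species
#'
#' The northernmost trawl station where the species is present (catch > 0)
#' in a given year. The limit is flagged censored when it lies within one
#' transect spacing of the survey's northern coverage limit, i.e. the true
#' range edge may lie beyond the sampled domain.
#'
#' @param trawls trawl data frame (columns `year`, `lat`, plus one numeric
#'   catch column per species).
#' @param species species column name.
#' @param year survey year.
#' @param meta a [survey_meta()] table.
#' @param spacing transect spacing in degrees latitude (default 0.25) used
#'   for the censoring rule.
#' @return list with `limit` (degrees north, `NA` if the species was absent
#'   all year) and `censored` (logical).
#' @export
northern_limit <- function(trawls, species, year, meta, spacing = 0.25) {
  rows <- trawls$year == year
  if (!any(rows)) stop("northern_limit: no trawls in year ", year)
  if (!species %in% names(trawls))
    stop("northern_limit: no species column '", species, "'")
  present <- rows & !is.na(trawls[[species]]) & trawls[[species]] > 0
  if (!any(present)) return(list(limit = NA_real_, censored = FALSE))
  lim <- max(trawls$lat[present])
  cov <- meta$coverage_north_limit[match(year, meta$year)]
  censored <- !is.na(cov) && (cov - lim) <= spacing + 1e-9
  list(limit = lim, censored = censored)
}

#' Yearly northern-limit series for one species
#'
#' @inheritParams northern_limit
#' @return data frame of class `limit_series` with columns `year`, `limit`,
#'   `censored`, and attribute `species`.
#' @export
northern_limit_series <- function(trawls, species, meta, spacing = 0.25) {
  years <- sort(unique(trawls$year))
  res <- lapply(years, function(y) northern_limit(trawls, species, y, meta, spacing))
  structure(data.frame(year = years,
                       limit = vapply(res, `[[`, 0.0, "limit"),
                       censored = vapply(res, `[[`, TRUE, "censored")),
            species = species,
            class = c("limit_series", "data.frame"))
}

usable_limits <- function(limits, years, exclude_censored) {
  keep <- limits$year %in% years & !is.na(limits$limit)
  if (exclude_censored) keep <- keep & !limits$censored
  limits[keep, , drop = FALSE]
}

#' Two-period northward shift of a range limit
#'
#' Difference of mean northern limits between two survey periods, converted to
#' km (111.195 km per degree of latitude) and normalised per decade by the
#' difference of the period mean survey years (not a hard-coded 10 years:
#' survey years are uneven). Censored years are excluded by default.
#'
#' @param limits a [northern_limit_series()].
#' @param periodA_years,periodB_years integer years of the earlier/later
#'   period (e.g. `1995:2001` and `c(2002:2006, 2011, 2015)`).
#' @param exclude_censored drop coverage-censored years (default TRUE).
#' @param km_per_deg km per degree of latitude (default [KM_PER_DEG_LAT]).
#' @return list of class `shift_estimate`: mean limits and mean survey years
#'   per period, `delta_lat`, `shift_km_per_decade`, and the years used.
#' @export
period_shift <- function(limits, periodA_years, periodB_years,
                         exclude_censored = TRUE,
                         km_per_deg = KM_PER_DEG_LAT) {
  a <- usable_limits(limits, periodA_years, exclude_censored)
  b <- usable_limits(limits, periodB_years, exclude_censored)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("period_shift: need at least 2 usable limits per period (got ",
         nrow(a), " and ", nrow(b), ")")
  dt <- mean(b$year) - mean(a$year)
  if (dt <= 0) stop("period_shift: period B must be later than period A")
  dlat <- mean(b$limit) - mean(a$limit)
  structure(list(species = attr(limits, "species"),
                 mean_limit_A = mean(a$limit), mean_limit_B = mean(b$limit),
                 mean_year_A = mean(a$year), mean_year_B = mean(b$year),
                 delta_lat = dlat,
                 shift_km_per_decade = dlat * km_per_deg / dt * 10,
                 years_A = a$year, years_B = b$year),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %s: %+.1f km/decade (%.2f -> %.2f degN, %g -> %g)\n",
              if (is.null(x$species)) "?" else x$species,
              x$shift_km_per_decade, x$mean_limit_A, x$mean_limit_B,
              x$mean_year_A, x$mean_year_B))
  invisible(x)
}

# Shared two-period bootstrap: resample (x, year) pairs with replacement
# within each period and recompute the statistic. stat_fun(xa, ya, xb, yb)
# must be vectorisable over resample rows; here it is applied via matrices.
bootstrap_two_period <- function(xa, ya, xb, yb, stat, n_boot, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  na <- length(xa); nb <- length(xb)
  ia <- matrix(sample.int(na, n_boot * na, replace = TRUE), n_boot, na)
  ib <- matrix(sample.int(nb, n_boot * nb, replace = TRUE), n_boot, nb)
  stat(matrix(xa[ia], n_boot, na), matrix(ya[ia], n_boot, na),
       matrix(xb[ib], n_boot, nb), matrix(yb[ib], n_boot, nb))
}

boot_p_two_sided <- function(delta_star, n_boot) {
  p <- 2 * min(sum(delta_star <= 0), sum(delta_star >= 0)) / n_boot
  min(1, max(2 / n_boot, p))
}

#' Bootstrap inference on a two-period range shift
#'
#' Resamples survey years (the exchangeable unit) with replacement within each
#' period and recomputes the difference of period mean limits each time. The
#' km-per-decade conversion uses the observed period mean survey years: the
#' survey design is deterministic, only the limits are random, so a
#' degenerate resample space yields a single-point interval. Reports the 95%
#' percentile confidence interval and the two-sided bootstrap p-value
#' `2 * min(#(delta* <= 0), #(delta* >= 0)) / n_boot`, floored at `2/n_boot`
#' and capped at 1. Deterministic given `seed`, and invariant to record
#' order (years are sorted before resampling).
#'
#' @inheritParams period_shift
#' @param n_boot number of resamples (default 10000).
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return the [period_shift()] estimate augmented with `ci` (length-2,
#'   km/decade), `p_value`, `n_boot`, `seed`.
#' @export
bootstrap_shift <- function(limits, periodA_years, periodB_years,
                            n_boot = 10000, seed = 1,
                            exclude_censored = TRUE, conf = 0.95,
                            km_per_deg = KM_PER_DEG_LAT) {
  est <- period_shift(limits, periodA_years, periodB_years,
                      exclude_censored, km_per_deg)
  a <- usable_limits(limits, periodA_years, exclude_censored)
  b <- usable_limits(limits, periodB_years, exclude_censored)
  a <- a[order(a$year), ]; b <- b[order(b$year), ]
  dt <- est$mean_year_B - est$mean_year_A
  delta_star <- bootstrap_two_period(
    a$limit, a$year, b$limit, b$year,
    stat = function(xa, ya, xb, yb)
      (rowMeans(xb) - rowMeans(xa)) * km_per_deg / dt * 10,
    n_boot = n_boot, seed = seed)
  alpha <- (1 - conf) / 2
  est$ci <- unname(stats::quantile(delta_star, c(alpha, 1 - alpha), type = 7))
  est$p_value <- boot_p_two_sided(delta_star, n_boot)
  est$n_boot <- n_boot
  est$seed <- seed
  est
}

#' Linear trend of a northern-limit series
#'
#' [linear_trend()] applied to `(year, limit * km_per_deg)`: the slope is a
#' northward speed in km per decade with Pearson r and p.
#'
#' @inheritParams period_shift
#' @param exclude_censored drop coverage-censored years (default TRUE).
#' @return a [linear_trend()] `trend_result` (slope in km/decade).
#' @export
limit_trend <- function(limits, exclude_censored = TRUE,
                        km_per_deg = KM_PER_DEG_LAT) {
  keep <- !is.na(limits$limit)
  if (exclude_censored) keep <- keep & !limits$censored
  linear_trend(limits$year[keep], limits$limit[keep] * km_per_deg)
}

#' Year-by-latitude biomass matrix (Hovmoller)
#'
#' Sums acoustic backscatter (NASC) per half-open latitude bin and survey
#' year. Years listed in `meta` with `has_biomass = FALSE` appear as
#' all-missing columns; bins never observed are zero within biomass years.
#'
#' @param bins data frame with columns `year`, `bin_lo`, `bin_hi`, `nasc`
#'   (optionally filtered to one species).
#' @param meta optional [survey_meta()]; adds missing columns for
#'   no-biomass years.
#' @return numeric matrix, rows = latitude bins (named by `bin_lo`), columns
#'   = years.
#' @export
hovmoller <- function(bins, meta = NULL) {
  years <- sort(unique(c(bins$year, if (!is.null(meta)) meta$year)))
  lo <- sort(unique(bins$bin_lo))
  m <- matrix(0, length(lo), length(years),
              dimnames = list(as.character(lo), as.character(years)))
  agg <- stats::aggregate(nasc ~ bin_lo + year, data = bins, FUN = sum)
  m[cbind(match(agg$bin_lo, lo), match(agg$year, years))] <- agg$nasc
  if (!is.null(meta)) {
    off <- meta$year[!meta$has_biomass]
    m[, as.character(off)[as.character(off) %in% colnames(m)]] <- NA_real_
    absent <- setdiff(years, c(bins$year, off))
    m[, as.character(absent)] <- NA_real_
  }
  m
}

#' Fraction of biomass north of a boundary latitude
#'
#' Per year, the share of summed NASC in bins whose southern edge is at or
#' north of `boundary_lat`. Years with zero total are missing. Complementary
#' fractions (north + south) sum to 1 by construction.
#'
#' @param bins data frame as in [hovmoller()].
#' @param boundary_lat boundary latitude, degrees north (default 21, Cape
#'   Blanc).
#' @return data frame with columns `year`, `fraction`.
#' @export
fraction_north <- function(bins, boundary_lat = 21) {
  years <- sort(unique(bins$year))
  frac <- vapply(years, function(y) {
    b <- bins[bins$year == y, ]
    tot <- sum(b$nasc)
    if (tot <= 0) return(NA_real_)
    sum(b$nasc[b$bin_lo >= boundary_lat]) / tot
  }, 0.0)
  data.frame(year = years, fraction = frac)
}

#' Bootstrap test on a two-period change in yearly fractions
#'
#' Same resampling contract as [bootstrap_shift()], applied to the yearly
#' fraction values: years are resampled with replacement within each period
#' and the difference of period means recomputed.
#'
#' @param fractions data frame from [fraction_north()].
#' @param periodA_years,periodB_years integer years of each period.
#' @param n_boot,seed,conf as in [bootstrap_shift()].
#' @return list with `delta` (mean B - mean A), `mean_A`, `mean_B`, `ci`,
#'   `p_value`, `n_boot`, `seed`.
#' @export
bootstrap_fraction <- function(fractions, periodA_years, periodB_years,
                               n_boot = 10000, seed = 1, conf = 0.95) {
  a <- fractions[fractions$year %in% periodA_years & !is.na(fractions$fraction), ]
  b <- fractions[fractions$year %in% periodB_years & !is.na(fractions$fraction), ]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("bootstrap_fraction: need at least 2 usable years per period")
  a <- a[order(a$year), ]; b <- b[order(b$year), ]
  delta_star <- bootstrap_two_period(
    a$fraction, a$year, b$fraction, b$year,
    stat = function(xa, ya, xb, yb) rowMeans(xb) - rowMeans(xa),
    n_boot = n_boot, seed = seed)
  alpha <- (1 - conf) / 2
  list(delta = mean(b$fraction) - mean(a$fraction),
       mean_A = mean(a$fraction), mean_B = mean(b$fraction),
       ci = unname(stats::quantile(delta_star, c(alpha, 1 - alpha), type = 7)),
       p_value = boot_p_two_sided(delta_star, n_boot),
       n_boot = n_boot, seed = seed)
}
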