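# Run configuration and the end-to-end pipeline: simulate -> upwelling ->
# band series -> trends -> chlorophyll calibration -> isotherms -> range
# shifts -> biomass partition.

#' Pipeline run configuration
#'
#' Every analysis parameter defaults to the study's stated value where one
#' exists: 100 km coastal strip, five latitude bands, isotherms
#' {18.5, 20, 22, 24} degC with climatology periods 1982--2001 vs 2002--2021,
#' biological periods 1995--2001 vs 2002--2015, Cape Blanc boundary 21 degN,
#' 10,000 bootstrap resamples.
#'
#' @param world a [world_config()] describing the synthetic inputs (or `NULL`
#'   when fields/surveys are supplied directly to [run_pipeline()]).
#' @param strip_width_km coastal strip width (default 100).
#' @param offshore_km outer limit of the offshore isotherm band (default 300).
#' @param bands list of [area_band()]s (default [default_area_bands()]).
#' @param isotherms isotherm temperatures, degC.
#' @param clim_periodA,clim_periodB climatology year ranges.
#' @param bio_periodA,bio_periodB biological comparison year sets.
#' @param boundary_lat biomass partition boundary (default 21 degN).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for all run-level randomness.
#' @param out_dir optional directory where tables and the report are written.
#' @return list of class `run_config`.
#' @export
run_config <- function(world = world_config(), strip_width_km = 100,
                       offshore_km = 300, bands = default_area_bands(),
                       isotherms = c(18.5, 20, 22, 24),
                       clim_periodA = 1982:2001, clim_periodB = 2002:2021,
                       bio_periodA = 1995:2001,
                       bio_periodB = c(2002:2006, 2011, 2015),
                       boundary_lat = 21, n_boot = 10000, seed = 1,
                       out_dir = NULL) {
  structure(list(world = world, strip_width_km = strip_width_km,
                 offshore_km = offshore_km, bands = bands,
                 isotherms = isotherms,
                 clim_periodA = clim_periodA, clim_periodB = clim_periodB,
                 bio_periodA = bio_periodA, bio_periodB = bio_periodB,
                 boundary_lat = boundary_lat, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

band_trend_rows <- function(series_list, variable, periods, bands) {
  rows <- list()
  for (bi in seq_along(series_list)) {
    for (pn in names(periods)) {
      yrs <- periods[[pn]]
      ann <- annual_mean(series_list[[bi]])
      ann <- ann[ann$year %in% yrs, ]
      tr <- tryCatch(linear_trend(ann), error = function(e) NULL)
      if (is.null(tr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variable = variable, band = bands[[bi]]$id, period = pn,
        slope_per_decade = tr$slope_per_decade, r = tr$pearson_r,
        p = tr$p_value, n = tr$n, stars = star_code(tr$p_value))
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: world simulation, upwelling index, coastal-strip band
#' series, trend analysis (long monitoring and survey-era periods),
#' chlorophyll cross-calibration and merging, two-period isotherm shifts,
#' per-species range-shift estimation with bootstrap inference, and the
#' biomass partition about the boundary latitude. Each stage failure is
#' reported with the stage name. The report is fully reproducible from the
#' configuration (including its seeds); if `config$out_dir` is set, tidy
#' tables and a JSON report are written there.
#'
#' @param config a [run_config()].
#' @param world optional pre-built [build_world()] result (skips simulation).
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config = run_config(), world = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (is.null(world))
    world <- stage("simulate", build_world(config$world))
  grid <- world$grid; dist <- world$dist
  bands <- Filter(function(b) b$lat_lo < max(dist$lat) &&
                    b$lat_hi > min(dist$lat), config$bands)
  mask <- stage("mask",
                coastal_mask(grid, world$coast, config$strip_width_km, dist))

  if (is.null(world$wind)) stop("pipeline stage 'upwelling' failed: wind fields missing from inputs", call. = FALSE)
  upw <- stage("upwelling",
               ekman_index_field(world$wind$u, world$wind$v, world$coast,
                                 mask, bands))
  speed_field <- stage("wind_speed", {
    s <- sqrt(world$wind$u$data^2 + world$wind$v$data^2)
    grid_field(s, world$wind$u$lat, world$wind$u$lon, world$wind$u$time,
               "wind_speed", "m s-1")
  })

  series <- stage("band_series", {
    list(sst = lapply(bands, function(b) area_series(world$sst, mask, b)),
         wind = lapply(bands, function(b) area_series(speed_field, mask, b)),
         upwelling = upw$series,
         chl_seawifs = lapply(bands, function(b)
           area_series(world$chl$seawifs, mask, b)),
         chl_modis = lapply(bands, function(b)
           area_series(world$chl$modis, mask, b)))
  })

  chl_merged <- stage("chl_calibration", lapply(seq_along(bands), function(i) {
    fit <- fit_cross_calibration(series$chl_seawifs[[i]],
                                 series$chl_modis[[i]])
    list(fit = fit,
         series = apply_and_merge(series$chl_seawifs[[i]],
                                  series$chl_modis[[i]], fit))
  }))

  periods <- list(
    lem_sst = config$clim_periodA[1]:config$clim_periodB[length(config$clim_periodB)],
    bss = config$bio_periodA[1]:config$bio_periodB[length(config$bio_periodB)])
  trends <- stage("trends", rbind(
    band_trend_rows(series$sst, "sst", periods, bands),
    band_trend_rows(series$wind, "wind_speed", periods, bands),
    band_trend_rows(series$upwelling, "upwelling_index", periods, bands),
    band_trend_rows(lapply(chl_merged, `[[`, "series"), "chl", periods,
                    bands)))

  iso <- stage("isotherms", {
    climA <- period_mean(world$sst, config$clim_periodA)
    climB <- period_mean(world$sst, config$clim_periodB)
    list(shifts = isotherm_shift(climA, climB, config$isotherms, dist,
                                 config$strip_width_km, config$offshore_km),
         anomaly_mean = mean(anomaly_map(climB, climA), na.rm = TRUE))
  })

  shifts <- stage("rangeshift", {
    sp_names <- setdiff(names(world$surveys$trawls),
                        c("year", "date", "lat", "lon"))
    rows <- lapply(sp_names, function(s) {
      lim <- northern_limit_series(world$surveys$trawls, s,
                                   world$surveys$meta,
                                   config$world$surveys$transect_spacing)
      bs <- tryCatch(
        bootstrap_shift(lim, config$bio_periodA, config$bio_periodB,
                        n_boot = config$n_boot, seed = config$seed),
        error = function(e) NULL)
      tr <- tryCatch(limit_trend(lim), error = function(e) NULL)
      data.frame(species = s,
                 shift_km_per_decade = if (is.null(bs)) NA else bs$shift_km_per_decade,
                 ci_lo = if (is.null(bs)) NA else bs$ci[1],
                 ci_hi = if (is.null(bs)) NA else bs$ci[2],
                 p_boot = if (is.null(bs)) NA else bs$p_value,
                 trend_km_per_decade = if (is.null(tr)) NA else tr$slope_per_decade,
                 trend_p = if (is.null(tr)) NA else tr$p_value,
                 n_censored = sum(lim$censored, na.rm = TRUE))
    })
    do.call(rbind, rows)
  })

  biomass <- stage("biomass", {
    focal <- config$world$fraction$species
    bins <- world$surveys$acoustic
    bins_f <- bins[bins$species == focal, ]
    frac <- fraction_north(bins_f, config$boundary_lat)
    bt <- bootstrap_fraction(frac, config$bio_periodA, config$bio_periodB,
                             n_boot = config$n_boot, seed = config$seed)
    list(hovmoller = hovmoller(bins_f, world$surveys$meta),
         fraction = frac, test = bt)
  })

  warnings <- c(
    if (any(!world$surveys$meta$has_biomass))
      paste("no acoustic biomass for year(s):",
            paste(world$surveys$meta$year[!world$surveys$meta$has_biomass],
                  collapse = ", ")),
    if (any(shifts$n_censored > 0))
      paste("coverage-censored limits excluded for:",
            paste(shifts$species[shifts$n_censored > 0], collapse = ", ")))

  report <- structure(list(
    config = config, seed = config$seed,
    constants = unclass(physical_constants()),
    trends = trends,
    chl_calibration = lapply(chl_merged, function(x) unclass(x$fit)),
    isotherm_shifts = iso$shifts, sst_anomaly_mean = iso$anomaly_mean,
    range_shifts = shifts,
    biomass_fraction = biomass$fraction, biomass_test = biomass$test,
    hovmoller = biomass$hovmoller,
    warnings = warnings,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, sprintf("(%.1f s)\n", x$elapsed_s))
  cat("  trends:", nrow(x$trends), "rows;",
      "range shifts:", nrow(x$range_shifts), "species;",
      "isotherms:", nrow(x$isotherm_shifts), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Tidy CSV tables (trends, range shifts, isotherm shifts, biomass fraction)
#' plus a JSON report echoing the configuration, seed and physical constants,
#' sufficient to re-run bit-identically.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$trends, file.path(dir, "trends.csv"),
                   row.names = FALSE)
  utils::write.csv(report$range_shifts, file.path(dir, "range_shifts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$isotherm_shifts,
                   file.path(dir, "isotherm_shifts.csv"), row.names = FALSE)
  utils::write.csv(report$biomass_fraction,
                   file.path(dir, "biomass_fraction.csv"), row.names = FALSE)
  serializable <- report
  serializable$config$bands <- lapply(report$config$bands, unclass)
  serializable$config$world <- unclass(report$config$world)
  serializable$hovmoller <- NULL
  jsonlite::write_json(lapply(serializable, unclass),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}

#' Deterministic digest of a run report
#'
#' JSON serialisation of the reproducible part of a report (timing and
#' output paths stripped); two runs from the same configuration must give
#' identical digests.
#'
#' @param report a `run_report`.
#' @return a single character string.
#' @export
report_digest <- function(report) {
  x <- unclass(report)
  x$elapsed_s <- NULL
  x$config$out_dir <- NULL
  x$config$bands <- lapply(x$config$bands, unclass)
  x$config$world <- unclass(x$config$world)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                   force = TRUE)
}
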