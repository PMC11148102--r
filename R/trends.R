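# Temporal aggregation and least-squares trend analysis with Pearson
# significance, for band series and per-cell maps.

#' Centered 12-term moving average
#'
#' The standard seasonal smoother for monthly series: a 13-point centered
#' filter with half weights on the two extreme months,
#' `[0.5, 1, ..., 1, 0.5] / 12`. It removes a pure 12-month cycle entirely and
#' passes a linear trend unchanged. Values are undefined (missing) near edges
#' and gaps.
#'
#' @param series a [monthly_series()].
#' @return a [monthly_series()] on the same month grid with smoothed values.
#' @export
moving_average_12 <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  reg <- regularize_months(series)
  if (nrow(reg) < 13)
    stop("moving_average_12: need at least 12 consecutive months")
  w <- c(0.5, rep(1, 11), 0.5) / 12
  sm <- as.numeric(stats::filter(reg$value, w, sides = 2))
  monthly_series(reg$year, reg$month, sm,
                 variable = attr(series, "variable"),
                 units = attr(series, "units"), band = attr(series, "band"))
}

#' Calendar-year means of a monthly series
#'
#' Years with fewer than `min_months` non-missing months are set missing.
#'
#' @param series a [monthly_series()].
#' @param min_months minimum months required per year (default 9).
#' @return data frame with columns `year`, `value` (one row per year present).
#' @export
annual_mean <- function(series, min_months = 9) {
  stopifnot(inherits(series, "monthly_series"))
  ok <- !is.na(series$value)
  years <- sort(unique(series$year))
  n <- vapply(years, function(y) sum(ok & series$year == y), 0L)
  v <- vapply(years, function(y) mean(series$value[series$year == y], na.rm = TRUE),
              0.0)
  v[n < min_months] <- NA_real_
  v[!is.finite(v)] <- NA_real_
  data.frame(year = years, value = v)
}

#' Least-squares linear trend with Pearson significance
#'
#' Ordinary least squares of `value` on `year`; the slope is reported per
#' decade (`10 * slope`). Significance is the two-sided p-value of the Pearson
#' correlation, `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom. A zero-variance response is the degenerate case: slope 0, r 0,
#' p 1.
#'
#' @param year numeric years (or a 2-column data frame `(year, value)`).
#' @param value response values; `NA` pairs are dropped.
#' @return an object of class `trend_result`: list with `slope_per_decade`,
#'   `intercept`, `pearson_r`, `p_value`, `n`.
#' @examples
#' linear_trend(2000:2004, c(10.0, 10.1, 10.4, 10.3, 10.7))
#' @export
linear_trend <- function(year, value = NULL) {
  if (is.null(value)) {
    stopifnot(is.data.frame(year), ncol(year) >= 2)
    value <- year[[2]]; year <- year[[1]]
  }
  keep <- !is.na(year) & !is.na(value)
  x <- as.double(year[keep]); y <- as.double(value[keep])
  if (length(unique(x)) < 3)
    stop("linear_trend: need at least 3 distinct years")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (syy == 0) {
    res <- list(slope_per_decade = 0, intercept = my, pearson_r = 0,
                p_value = 1, n = n)
    return(structure(res, class = "trend_result"))
  }
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r <- max(-1, min(1, sxy / sqrt(sxx * syy)))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(slope_per_decade = 10 * slope, intercept = my - slope * mx,
                 pearson_r = r, p_value = p, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope %.4g /decade, r = %.4f, p = %.4g%s (n = %d)\n",
              x$slope_per_decade, x$pearson_r, x$p_value,
              star_code(x$p_value), x$n))
  invisible(x)
}

#' Per-cell trend map with significance mask
#'
#' Applies [linear_trend()] cell-wise to annual means of a gridded field,
#' vectorised across cells. Cells with fewer than 3 usable years are missing.
#'
#' @param field a [grid_field()].
#' @param years optional year range (integer vector) to restrict to.
#' @param min_months minimum months per year for [annual_mean()] semantics.
#' @param p_threshold significance threshold for the mask (default 0.05).
#' @return list with matrices `slope_per_decade`, `p_value`, and logical
#'   `significant` (`p < p_threshold`), plus `n_years`.
#' @export
trend_map <- function(field, years = NULL, min_months = 9, p_threshold = 0.05) {
  stopifnot(inherits(field, "grid_field"))
  tm <- field$time
  keep <- if (is.null(years)) rep(TRUE, nrow(tm)) else tm$year %in% years
  yrs <- sort(unique(tm$year[keep]))
  ncell <- length(field$lat) * length(field$lon)
  flat <- matrix(field$data, nrow = ncell)[, keep, drop = FALSE]
  # annual means per cell (ncell x nyear)
  ann <- matrix(NA_real_, ncell, length(yrs))
  for (j in seq_along(yrs)) {
    cols <- which(tm$year[keep] == yrs[j])
    block <- flat[, cols, drop = FALSE]
    cnt <- rowSums(!is.na(block))
    m <- rowMeans(block, na.rm = TRUE)
    m[cnt < min_months] <- NA_real_
    ann[, j] <- m
  }
  ok <- !is.na(ann)
  n <- rowSums(ok)
  x <- matrix(yrs, ncell, length(yrs), byrow = TRUE)
  x[!ok] <- NA
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(ann, na.rm = TRUE)
  dx <- x - mx; dy <- ann - my
  dx[!ok] <- 0; dy[!ok] <- 0
  sxx <- rowSums(dx^2); syy <- rowSums(dy^2); sxy <- rowSums(dx * dy)
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  r <- pmax(-1, pmin(1, r))
  tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n - 2, 1))
  zerovar <- syy == 0
  slope[zerovar] <- 0; r[zerovar] <- 0; p[zerovar] <- 1
  bad <- n < 3 | sxx == 0
  slope[bad] <- NA; r[bad] <- NA; p[bad] <- NA
  dims <- c(length(field$lat), length(field$lon))
  list(slope_per_decade = matrix(10 * slope, dims[1], dims[2]),
       p_value = matrix(p, dims[1], dims[2]),
       significant = matrix(!is.na(p) & p < p_threshold, dims[1], dims[2]),
       n_years = matrix(n, dims[1], dims[2]))
}

#' Significance star codes
#'
#' `""` for p >= 0.05, `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for
#' p < 0.001 and `"****"` for p < 0.0001. (Display captions sometimes print
#' these thresholds with a `>` sign; they are significance levels, i.e.
#' strict upper bounds on p.)
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
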