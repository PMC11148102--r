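# Cross-calibration of two overlapping chlorophyll sensor series and merging
# into one continuous record.

#' Fit a log-space cross-calibration between two sensor series
#'
#' Ordinary least squares of `log10(ref)` on `log10(other)` over paired months
#' of the overlap window: `log10(ref) = b0 + b1 * log10(other)`. A pure
#' multiplicative bias `other = ref * rho` gives `b1 = 1`,
#' `b0 = -log10(rho)`. At least 24 paired months are required.
#'
#' @param ref reference-sensor [monthly_series()] (chlorophyll, mg m^-3,
#'   all values > 0).
#' @param other other-sensor [monthly_series()].
#' @param overlap_years integer years of the common period (default
#'   2003:2010).
#' @return list of class `chl_calibration` with `b0`, `b1`, `n_pairs`,
#'   `overlap_years`.
#' @export
fit_cross_calibration <- function(ref, other, overlap_years = 2003:2010) {
  stopifnot(inherits(ref, "monthly_series"), inherits(other, "monthly_series"))
  key_r <- ref$year * 12L + ref$month
  key_o <- other$year * 12L + other$month
  in_r <- ref$year %in% overlap_years & !is.na(ref$value)
  m <- match(key_r[in_r], key_o)
  ok <- !is.na(m) & !is.na(other$value[m])
  x <- other$value[m[ok]]
  y <- ref$value[in_r][ok]
  if (length(x) < 24)
    stop("fit_cross_calibration: need >= 24 paired overlap months, got ",
         length(x))
  if (any(x <= 0) || any(y <= 0))
    stop("fit_cross_calibration: chlorophyll values must be positive")
  lx <- log10(x); ly <- log10(y)
  vx <- sum((lx - mean(lx))^2)
  b1 <- if (vx == 0) 1 else sum((lx - mean(lx)) * (ly - mean(ly))) / vx
  b0 <- mean(ly) - b1 * mean(lx)
  structure(list(b0 = b0, b1 = b1, n_pairs = length(x),
                 overlap_years = range(overlap_years)),
            class = "chl_calibration")
}

#' @export
print.chl_calibration <- function(x, ...) {
  cat(sprintf("<chl_calibration> log10(ref) = %.5g + %.5g * log10(other) (%d paired months, overlap %d-%d)\n",
              x$b0, x$b1, x$n_pairs, x$overlap_years[1], x$overlap_years[2]))
  invisible(x)
}

#' Apply a cross-calibration and merge two sensor series
#'
#' The other sensor is mapped through `10^(b0 + b1 * log10(value))` (so
#' positivity is preserved) and the merged record uses the reference sensor
#' before `switch_year` and the corrected other sensor from `switch_year`
#' onward.
#'
#' @param ref,other [monthly_series()] as in [fit_cross_calibration()].
#' @param coeffs a `chl_calibration` fit.
#' @param switch_year first year taken from the corrected other sensor
#'   (default 2011).
#' @return a merged [monthly_series()] spanning the union of both spans, with
#'   no duplicate months.
#' @export
apply_and_merge <- function(ref, other, coeffs, switch_year = 2011) {
  stopifnot(inherits(coeffs, "chl_calibration"))
  corrected <- 10^(coeffs$b0 + coeffs$b1 * log10(other$value))
  keep_r <- ref$year < switch_year
  keep_o <- other$year >= switch_year
  monthly_series(c(ref$year[keep_r], other$year[keep_o]),
                 c(ref$month[keep_r], other$month[keep_o]),
                 c(ref$value[keep_r], corrected[keep_o]),
                 variable = attr(ref, "variable"),
                 units = attr(ref, "units"), band = attr(ref, "band"))
}
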