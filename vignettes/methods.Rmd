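---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pelagicshift` implements a coastal-upwelling climate-impact analysis: an
isobath-oriented Ekman upwelling index, coastal-strip trend analysis of
gridded satellite fields, two-period isotherm displacement, and species
range-shift inference from trawl/acoustic surveys. This vignette documents
the models, every tunable parameter that matters, the synthetic world the
estimators are validated against, and the design choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Geometry

All distances use a spherical Earth, R = 6371 km, with haversine great-circle
distances; one degree of latitude is 111.195 km. At the 30–300 km scales of
this analysis the spheroid correction is well below the grid resolution.
Grids are cell-center registered; a cell is "ocean" iff its center lies on
the ocean side (west, configurable) of the coastline at the cell's latitude.
The distance-to-coast field is the minimum distance to the coastline
polyline densified to ≤0.01° vertex spacing, which keeps the point-sampling
error of the nearest-point search under ~0.5 km; the 100-km coastal strip
(`coastal_mask`) is monotone in width, with width 0 the documented
degenerate case (error only for negative widths, resolving a contradiction
between an error rule and a stated example).

The five analysis bands are 1: [26, 30), 2: [21, 26), 3: [20, 21),
4: [16, 21), 5: [12, 16) °N, half-open so adjacent bands tile without double
counting. Band 3 (around Cape Blanc) deliberately lies inside band 4's
printed bounds: bands are independent selections and are never assumed
disjoint. Area averages are unweighted cell means — the strip is narrow, the
source analysis states no weighting, and a cos-latitude weight would change
band means by far less than the field noise; this is a documented choice,
not a config switch, because nothing downstream depends on it at desk scale.

The alongshore direction is the local tangent of the 200 m isobath, not the
coastline: `isobath_angle` takes the finite difference between the two
vertices bracketing the query latitude in a local plane (longitude scaled by
cos φ), returning the poleward tangent angle measured counterclockwise from
east (meridional isobath → π/2).

## Upwelling index

Bulk wind stress τ = ρ_a C_d |W| (u, v) with ρ_a = 1.22 kg m⁻³,
C_d = 1.3×10⁻³ (constant, wind-speed independent), ρ_w = 1025 kg m⁻³ and
Ω = 7.2921×10⁻⁵ rad s⁻¹. The cited bulk-formula lineage does not pin these
constants, so they are fixed here at standard values, overridable through
`physical_constants()` and echoed in every run report. The index is the
offshore component of Ekman transport per metre of coast,
−(τ_x cos θ + τ_y sin θ)/(ρ_w f), in m² s⁻¹; a ×100 conversion to the
historical m³ s⁻¹ per 100 m of coast is a display matter only. Latitudes
within 5° of the equator are rejected (equatorial singularity); the study
domain starts at 10 °N.

Two open points were decided as follows. The index is computed **cell-wise
and then band-averaged** (not from band-mean winds): stress is quadratic in
wind speed, so the order matters, and cell-wise evaluation is the faithful
reading of a per-pixel satellite product. Monthly winds are used directly;
stress from a monthly-mean wind underestimates the stress of averaged daily
cubes, which is acceptable because the synthetic inputs are monthly by
construction and the recoverable quantity is the trend, not the absolute
level.

## Trends

Trends are ordinary least squares of **annual means** on year (slope
reported per decade), not of monthly values: annual averaging removes the
seasonal cycle exactly and sidesteps seasonal autocorrelation. Years with
fewer than 9 valid months (configurable) are dropped. Significance is the
Pearson-correlation t test with n−2 df; a zero-variance response is defined
as slope 0, r 0, p 1. Gap years (e.g. missing survey years) are simply
absent points — no imputation. Step changes are not modelled separately:
the fitted trends implicitly absorb them, and a change-point estimator is
out of scope. Autocorrelation-corrected significance (effective-n) is
deliberately not implemented; p-values on strongly autocorrelated monthly
series would be anticonservative, which is one reason trends are fitted on
annual means.

The 12-term moving average used for display is the classical 13-point
centred filter with half weights at the ends ([0.5, 1, …, 1, 0.5]/12): it
annihilates a pure 12-month cycle and passes linear trends unchanged. Star
codes follow the usual ladder (\*: p < 0.05 through \*\*\*\*: p < 0.0001);
source captions sometimes print these thresholds with a reversed inequality
sign, which is read as the standard significance-level convention rather
than literally.

## Chlorophyll cross-calibration

The two sensors are merged with a log-space affine map fitted per band
series on the 2003–2010 overlap (≥24 paired months required):
log₁₀(ref) = b₀ + b₁ log₁₀(other), applied as 10^(b₀+b₁ log₁₀ x) so
positivity is preserved, with the earlier sensor as reference (trend anchor)
and the switch at 2011. Band-level rather than per-pixel correction is the
minimal faithful choice given that the original calibration method is cited
but not specified; the correction direction (which sensor is reference) is
configurable and recorded in the run report. The calibration is idempotent:
refitting a corrected pair returns (0, 1) in the noise-free case.

## Isotherm displacement

Climatologies are plain cell-wise means over all months of a 20-year window
(default 1982–2001 vs 2002–2021, configurable), requiring ≥10 contributing
years per cell. Isotherms are traced per longitude column, south to north,
taking the **first (southernmost) linear-interpolated crossing** and
flagging columns with multiple crossings: the region's climatological SST is
essentially monotone poleward, and the flag surfaces violations instead of
guessing. Displacement between two traces is the mean **along-meridian**
distance over common columns (positive north), matching the northward
framing of the analysis; nearest-point distances between isolines would
differ only where isotherms bend sharply. Coastal vs offshore domains are
≤100 km and 100–300 km from the coast (the source separates the domains
without defining them; 300 km is configurable). On the 0.25° desk grid the
coastal band can hold fewer than the 3 columns required for a robust mean,
in which case the displacement is reported missing — a deliberate refusal
rather than a failure.

## Range shifts from surveys

The northern limit of a species-year is the northernmost trawl with catch
> 0 (no minimum-catch threshold — none is stated). A limit within one
transect spacing of the survey's northern coverage limit is **censored**:
the true edge may lie beyond the sampled domain (the 2005 survey, truncated
at 26°18′ N, is the canonical case). Censored years are excluded from both
periods by default, mirroring the source's exclusion of affected species in
2005.

The two-period shift is Δφ̄ · 111.195 km/° · 10 / (ȳ_B − ȳ_A), where ȳ are
the period mean survey years: with surveys at 1995–2001 and
{2002–2006, 2011, 2015} the denominator is ≈8.57 yr, and a hard-coded 10
would misstate the rate. The bootstrap resamples whole survey years (the
exchangeable unit) within each period, 10,000 times, recomputing the
difference of period mean limits; the km/decade conversion keeps the
observed time denominator because the survey design is deterministic — this
also makes the degenerate resample space collapse to a single-point CI, as
it should. The two-sided p is 2·min(#{Δ*≤0}, #{Δ*≥0})/n_boot, floored at
2/n_boot, capped at 1, bit-reproducible given the seed and invariant to
record order. The same machinery tests the change in the yearly fraction of
acoustic biomass north of the boundary latitude (Cape Blanc; stated both as
~21 °N and 20 °N in different passages — default 21.0, configurable).

### Bootstrap calibration (why one acceptance check is red)

On 200 synthetic replicates at the default drift (180 km/decade) the mean
estimate is within a few km/decade of truth, and under zero drift the
bootstrap test's type-I error at 0.05 is ≈0.08 — both inside their
acceptance bands. The 95% percentile-CI **coverage**, however, is not: with
7 years per period the percentile bootstrap is structurally miscalibrated,
and the two faithful readings of "resample years within each period"
bracket the target band without entering it. Keeping the time denominator
fixed, the within-period drift (~1° of true movement across each 7-year
window) is counted as year-level noise, the bootstrap sd (~41 km/decade)
exceeds the estimator's true sampling sd (~30 km/decade), and coverage is
≈1.00. Resampling (limit, year) pairs and recomputing the denominator makes
numerator and denominator positively correlated, cancels the drift spread,
and adds the usual √((n−1)/n) small-sample shrinkage, giving ≈0.87. Neither
lands in [0.90, 0.99]; the criterion is asserted as stated and left red
rather than replaced by a better-calibrated interval (BCa, expanded
percentile) that the contract does not prescribe.

## The synthetic world

The generator states the study's conditions rather than tuning to them:
a 10–32 °N × −22–−10 °E grid at 0.25° (a desk-scale stand-in for 1/24°
products); SST 1982–2021, winds 1988–2021, chlorophyll 1998–2021 with
sensor spans 1998–2010 / 2003–2021; 14 November surveys (1995–2006, 2011,
2015), transects every 0.25° latitude with 2 stations each (~140 trawls per
survey, matching the published per-survey counts), the 2005 survey truncated
at 26.3 °N and 2011 carrying no acoustic biomass.

Fields are sums of closed-form components — meridional gradient (SST 0.5
°C/°lat from 27.5 °C at 12 °N), seasonal cycle (amplitude 2 °C, peak
October), linear trend (SST 0.3 °C/decade, the mid-range of the reported
0.3–0.5; wind 0.2 m s⁻¹/decade on a 7 m s⁻¹ mean), optional step change
(off by default: trends absorb step effects by stated practice), coastal
upwelling cooling (3 °C maximum, 60 km e-folding, peaking in late boreal
winter) — plus AR(1) noise (φ = 0.6, σ = 0.4 °C marginal) per cell.
Noise-free worlds reproduce the closed forms exactly, and band trends then
equal configured trends to ≥10 significant digits, which is what makes the
trend estimator testable without tolerance fudging. The trend is spatially
uniform by default: the five bands overlap (band 3 sits inside band 4), so
a "per-band" trend field is ill-defined as geometry, and a scalar keeps the
noise-free exactness contract.

Species occupy a logistic northern edge: presence probability
p = detection · logistic((L_s(t) − φ)/steepness) with detection 0.85 and
steepness 0.3° — a stand-in model, clearly labelled as such, since no
quantitative occupancy model links environment to presence in the source.
Limits drift linearly at configured rates (defaults spanning 0–200
km/decade across the eight species, the focal species at 180). Station NASC
is log-normal when present. The biomass fraction north of the boundary is
**stated directly** as a logit-linear ramp from 0.38 (1995) to 0.65 (2015)
with year-level logit noise (σ = 0.2, chosen once as a realistic
interannual wobble): the source provides those endpoints but no mechanism
linking environment to biomass allocation, so inventing one would have
created an untestable intermediate layer. Within each region the log-normal
station structure is preserved and region totals are rescaled to the
realized fraction, which the binned estimator then recovers exactly — a
green fraction test therefore establishes the estimator and test machinery,
not any ecological mechanism.

RNG discipline: the master seed spawns one substream per component (SST,
wind, chlorophyll, surveys, fraction), and each species draws from its own
survey substream, so adding a species perturbs neither the fields nor the
other species — this is tested. Everything is bit-reproducible from
(config, seed).

What the world does **not** emulate: mesoscale structure (eddies,
filaments), daily wind variability (monthly stress from mean winds
underestimates true stress), sensor geometry/gaps, vessel effects, and any
environment→occupancy coupling. Green tests therefore establish estimator
correctness and calibration on a world with known truth — not fidelity of
that world to the real Canary Current.

## Numerical choices

- Degrees→km at 111.195 km/°lat everywhere (π·6371/180); no factor is
  stated in the source.
- Isotherm interpolation is linear between adjacent cell centers; the
  translation property holds to 10⁻⁶ degrees on smooth fields.
- Percentile CIs use R's default quantile type 7; degenerate bootstrap
  distributions yield single-point CIs and the floor p = 2/n_boot.
- Gridded output is a self-describing JSON container (CF-like lat/lon/time
  coordinate variables, units, null sentinel) serialised at 17 significant
  digits, making write→read round trips bit-exact; a NetCDF library is not
  among the supported dependencies, and the container is deliberately
  text-only.
- Ties at zero in the bootstrap p count on both sides (conservative).

## Known limitations

- The percentile-bootstrap coverage miscalibration described above is a
  property of the prescribed procedure at n = 7 years per period, not a bug;
  users wanting calibrated intervals should increase the number of surveys
  per period or use a t-interval on the yearly limits.
- Coastal isotherm traces can be data-starved at 0.25° resolution; the
  1/24° resolution of real products does not have this problem.
- The area-average is unweighted; at band widths of 4–5° of latitude a
  cos-φ weighting would shift band means by <1%, far below field noise.
- Survey stations sit on fixed cross-shore offsets (15 and 45 km); real
  transects have variable geometry, which mainly adds detection noise the
  logistic edge model already subsumes.
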