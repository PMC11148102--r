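# pelagicshift

Tools for quantifying climate-driven distribution shifts of small pelagic
fish in an eastern boundary upwelling system, modelled on the southern
Canary Current off Northwest Africa (roughly 10–32 °N). The package is aimed
at fisheries oceanographers who have gridded satellite fields (SST, 10-m
winds, chlorophyll-a) and research-trawl / acoustic survey records, and who
want a tested, reproducible pipeline from raw monthly fields to range-shift
statistics — plus a fully parameterised synthetic world with recorded ground
truth, so every estimator can be validated against a known answer.

## What it computes

**Isobath-oriented Ekman upwelling index.** Wind stress from the bulk
formula τ = ρ_a·C_d·|W|·(u, v) with ρ_a = 1.22 kg m⁻³ and C_d = 1.3×10⁻³;
offshore Ekman transport per metre of coast

M·n̂ = −(τ_x cos θ + τ_y sin θ) / (ρ_w f),   f = 2Ω sin φ,

where θ is the local tangent angle of the 200 m isobath (used instead of the
coastline angle) and n̂ the offshore normal. Positive values are
upwelling-favourable. Computed cell-wise over a 100-km coastal strip, then
averaged into five latitude bands (26–30, 21–26, 20–21, 16–21, 12–16 °N).

**Trend analysis.** Least-squares linear trends of annual means, reported
per decade, with significance from the Pearson correlation
(t = r·√((n−2)/(1−r²)), n−2 df); per-cell trend maps with p < 0.05 masks; a
centred 12-term moving average for display series.

**Chlorophyll cross-calibration.** Two overlapping sensor series (emulating
SeaWiFS 1998–2010 and MODIS 2003–2021) are merged after an OLS fit of
log₁₀(ref) on log₁₀(other) over the 2003–2010 overlap.

**Isotherm displacement.** 20-year SST climatologies (1982–2001 vs
2002–2021), isotherms {18.5, 20, 22, 24 °C} traced per longitude column,
and the mean meridional displacement reported separately for the coastal
(≤100 km) and offshore (100–300 km) domains, in km.

**Range shifts from surveys.** Per species, the annual northern limit (the
northernmost trawl with presence), flagged as censored when it reaches the
survey's coverage limit; the two-period shift (1995–2001 vs 2002–2015)
converted to km/decade via 111.195 km/°lat and the difference of period mean
survey years; inference from a 10,000-resample year-level bootstrap
(percentile 95% CI, two-sided p floored at 2/n_boot); and a full-series
linear trend. Acoustic NASC is partitioned into 0.5° latitude bins
(Hovmöller matrix) and the fraction of biomass north of Cape Blanc (21 °N)
is tested between periods with the same bootstrap.

## Worked example

```r
library(pelagicshift)

# physics closed form: 10 m/s equatorward wind along a meridional coast, 21 N
s <- wind_stress(0, -10)
ekman_index(s$taux, s$tauy, pi / 2, 21)
#> [1] 2.960517        # m2/s per m of coast, offshore = upwelling-favourable

linear_trend(2000:2004, c(10.0, 10.1, 10.4, 10.3, 10.7))
#> <trend_result> slope 1.6 /decade, r = 0.9238, p = 0.02498* (n = 5)

# full synthetic-world pipeline (default world: SST trend 0.3 degC/decade,
# focal species drifting north at 180 km/decade, biomass fraction north of
# 21 N ramping 0.38 -> 0.65 over 1995-2015)
rep <- run_pipeline(run_config(seed = 1))
rep
#> <run_report> seed 1 (2.4 s)
#>   trends: 40 rows; range shifts: 8 species; isotherms: 4
#>   warnings: no acoustic biomass for year(s): 2011; coverage-censored
#>   limits excluded for: T_tre

subset(rep$trends, variable == "sst" & period == "lem_sst")[1:2, 1:5]
#>   variable band  period slope_per_decade         r
#> 1      sst    1 lem_sst        0.3017838 0.9967763
#> 3      sst    2 lem_sst        0.3020042 0.9983110

rep$isotherm_shifts
#>   temperature coastal_km offshore_km n_coastal n_offshore
#> 1        18.5         NA    136.1692        NA          7
#> 2        20.0         NA    134.2981        NA          7
#> 3        22.0   149.9808    135.7560         3          7
#> 4        24.0   105.5766    131.2860         5          7

subset(rep$range_shifts, species == "S_aur")[, 2:5]
#>   shift_km_per_decade    ci_lo    ci_hi p_boot
#> 1            199.2242 111.1949 282.6204  2e-04

rep$biomass_test[c("mean_A", "mean_B", "p_value")]
#> $mean_A [1] 0.4162277   $mean_B [1] 0.4971768   $p_value [1] 0.0012
```

Reading the output: band SST trends recover the configured 0.3 °C/decade;
the offshore isotherms move north by ~130–136 km between the two 20-year
periods (0.3 °C/decade × 20 yr ÷ 0.5 °C/°lat ≈ 133 km — the arithmetic
checks out); the focal species' estimated shift (199 km/decade, CI
111–283) brackets its true 180 km/decade drift; and the biomass fraction
north of 21 °N rises significantly between the two survey periods. Coastal
isotherm cells are sparse on the 0.25° desk-scale grid, so some coastal
displacements are reported as missing rather than guessed.

A command-line interface with `simulate / upwelling / trends / isotherms /
rangeshift / biomass / all` subcommands over saved intermediates lives in
`inst/scripts/pelagicshift-cli.R`:

```sh
Rscript inst/scripts/pelagicshift-cli.R simulate --dir run1 --seed 1
Rscript inst/scripts/pelagicshift-cli.R rangeshift --dir run1
```

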