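Package: pelagicshift
Title: Climate Trends and Range Shifts of Small Pelagic Fish in an
    Eastern Boundary Upwelling System
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify climate-driven distribution shifts of small
    pelagic fish in coastal upwelling systems, modelled on the southern
    Canary Current. Provides an isobath-oriented Ekman upwelling index from
    10-m winds, coastal-strip averaging and least-squares trend analysis of
    gridded satellite fields (SST, wind, chlorophyll-a with two-sensor
    cross-calibration), isotherm displacement between 20-year climatologies,
    species northern-range-limit extraction from trawl surveys with
    two-period bootstrap inference, latitudinal partitioning of acoustic
    biomass, and a fully parameterised synthetic-world generator with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
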