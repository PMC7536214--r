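Package: trawlshift
Title: Three-Dimensional Distribution Shifts of Fish in Standardized Trawl Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies shifts in the latitude, longitude and depth distribution
    of fish species sampled by a standardized groundfish trawl survey, and
    disentangles warming-driven shifts from abundance-driven shifts. Provides
    catch-per-unit-effort standardization, thermal affinity indices (thermal
    bias and stenothermy), a station/year/day-of-year linear model for an
    annual environmental temperature index, abundance-weighted annual
    centroids with geodesic shift vectors and rose-plot tables, pooled and
    spatially-structured location models with temperature and abundance
    covariates, shift predictions for a 1 degree Celsius warming and for an
    abundance doubling, and a cross-species synthesis report. A synthetic
    survey generator with known thermal niches and injected centroid drift
    supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
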