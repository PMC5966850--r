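Package: geoequity
Title: Health-Need Inequality Metrics for Commercial Geospatial Data Availability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how commercial geospatial data resources
    (geocoding services, travel-time data, neighbourhood statistics) are
    distributed relative to population health need. Converts provider
    coverage statements into ordinal availability scores, aggregates them
    into per-domain and overall resource indices by rank summation, and
    measures the mortality gradient across the resulting ranking with the
    slope index of inequality and the relative concentration index.
    Includes a district-level workflow relating geocoding success rates to
    a z-score census deprivation index, regression-based outlier
    diagnostics, and a seeded synthetic-data generator that emulates the
    statistical structure of the country and district inputs so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
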