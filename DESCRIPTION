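Package: firecomposite
Title: Superposed-Epoch Analysis of Soil Moisture and Biomass Anomalies
    Preceding Large Wildfires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for an observational, event-based analysis of the
    hydro-climatic conditions preceding the largest local wildfires on a
    regular latitude-longitude grid. The pipeline samples, per grid cell,
    the month with the largest burned area on record, applies a data-quality
    and population filter cascade, converts gridded soil moisture,
    temperature and vegetation-optical-depth fields into month-of-year
    z-score anomalies against a multi-year climatology, composites the
    anomalies across events by climate regime (long-term temperature by
    aridity boxes, humid versus arid split at aridity 2), and assesses
    significance with a Monte-Carlo null built from same-season,
    different-year resampled months. A synthetic-scene generator with a
    known truth record emulates the statistical structure of the satellite
    products so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ncdf4,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
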