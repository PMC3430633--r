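Package: lulctrends
Title: Annual Land-Cover Mapping and Decade-Scale Change Trends from
    Composite Vegetation-Index Time Series
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for annual land-use/land-cover (LULC)
    mapping from 16-day composite vegetation-index imagery and for
    decade-scale change-trend analysis of the resulting maps. Includes a
    synthetic-scene simulator (landscape partitions, prescribed cover
    trajectories, class phenologies, reliability gaps, paired-interpreter
    reference samples), percent-cover consensus labelling rules, temporal
    window statistics with reliability filtering, per-biome tiered
    random-forest classification with proximity-based outlier removal and
    out-of-bag accuracy assessment, per-municipality linear trend
    regressions with missing-year rules, and multi-scale net-change
    aggregation (municipality, ecoregion, biome, country) with hotspot
    tables and a rank-sum size comparison.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
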