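Package: covgrid
Title: Spatio-Temporal Harmonisation of Gridded Geospatial Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for harmonising heterogeneous geospatial
    source layers (land cover, elevation, climate, nighttime radiance,
    protected areas, roads, building footprints, built-up surface and
    volume stacks) into co-registered gridded covariates on a 3 arc-second
    WGS84 master grid, of the kind used as ancillary layers for dasymetric
    population mapping. Includes threshold-family inland-water masks,
    great-circle distance-to-feature transforms, iterative radiance
    outlier filtering around gas-flare and volcano sites, centroid- and
    intersection-based building-footprint gridding, multi-source built-up
    fusion with Nadaraya-Watson kernel height imputation, and seeded
    synthetic-fixture generators so the full pipeline runs without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    sp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
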