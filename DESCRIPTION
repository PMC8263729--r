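Package: habscape
Title: Habitat Quality, Land-Use Change and Urbanization Coupling on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Raster-style habitat quality modelling and urbanization coupling
    analysis on categorical land-use grids. Implements a threat-based habitat
    degradation and half-saturation quality model with distance-decay kernels,
    land-use transition accounting with habitat-quality change (HQCI) and
    contribution (CI) indices, basin-level urbanization indicators
    (nighttime-light, population, land urbanization rate), from-scratch
    ordinary least squares and geographically weighted regression with AICc
    bandwidth selection, and Kohonen self-organizing-map zoning of basins into
    green-development classes. A synthetic-landscape generator (clustered
    urban cores, epochal urban growth, correlated covariates, merged basin
    tessellations) makes the whole pipeline reproducible without external
    geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), mclust, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
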