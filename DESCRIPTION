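Package: pairscape
Title: Pairwise Landscape Connectivity Models for Landscape Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares families of landscape-connectivity models as predictors
    of pairwise genetic distance under maximum-likelihood population-effects
    (MLPE) mixed models. Implements gradient surface metrics on continuous
    habitat-suitability rasters, FRAGSTATS-style landscape-level metrics on
    categorical patch mosaics, least-cost-path and random-walk commute
    distances on conductance-weighted raster graphs, and an
    isolation-by-distance null model. Microsatellite genetic distances (R_ST
    under a stepwise mutation model and the proportion-of-shared-alleles
    distance D_PS) are computed from genotype tables. A synthetic-data module
    generates fractional-Brownian suitability surfaces, land-cover mosaics,
    sampling sites, forward-simulated microsatellite genotypes, and pairwise
    responses with planted MLPE structure, so the full comparison pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
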