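Package: habcomplex
Title: Geometric and Informational Metrics of Habitat Structural Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies habitat structural complexity from digital elevation
    models (heightmaps), elevation profiles and binary raster maps. Implements
    bias-aware fractal dimension estimation (box-counting with random grid
    origins and intermediate-scale restriction, and the variation method),
    rugosity with plane-of-best-fit slope correction and multi-resolution
    analysis, terrain ruggedness, slope/aspect, vector dispersion, and Shannon
    entropy of habitat composition. Ships simulators of fractional Brownian
    surfaces of known fractal dimension (midpoint displacement and Fourier
    synthesis), Koch-curve rasters and analytic fixtures, plus a reproducible
    pipeline that quantifies the scale-dependent bias of fractal dimension
    estimators on simulated surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
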