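Package: bharal
Title: Minimum Density and Habitat Selection of Mountain Ungulates from
    Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing total-count transect surveys of mountain
    ungulates such as the blue sheep (Pseudois nayaur). Implements terrain
    covariates from a digital elevation model (Horn slope and aspect,
    terrain ruggedness, D8 hydrology, cliff and stream extraction, distance
    surfaces), line-of-sight viewsheds around transects with minimum-density
    estimation from total counts, NDVI-based land-cover calibration, a
    used-available habitat-selection design with distance-weighted
    pseudo-absence sampling and adult-weighted binomial generalized additive
    models, and permutation-based variable importance. A synthetic-landscape
    generator with known ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
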