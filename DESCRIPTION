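Package: isokrig
Title: Stable-Isotope Isoscapes by Ordinary and Co-Kriging for
    Geographic Origin Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds delta-13C isoscapes for herbivorous insects (developed
    around the pine wilt vector Monochamus alternatus) from sparse site
    tables of isotope means and bioclimatic covariates.  Provides Pearson
    and variance-inflation-factor screening of covariate blocks, empirical
    direct and cross semivariograms with an eleven-family parametric model
    catalog, weighted-least-squares fitting and a linear model of
    coregionalization, ordinary kriging and ordinary co-kriging with
    leave-one-out cross-validation (RMSE, mean standardized error, RMSSE,
    average standard error), Moran's I permutation tests, Fisher-Jenks
    natural-breaks classification of the prediction surface, and assignment
    of unknown samples to origin regions.  A seeded coregionalized
    Gaussian-random-field generator produces synthetic site tables with the
    spatial structure the method assumes, so the whole pipeline is testable
    without external rasters.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
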