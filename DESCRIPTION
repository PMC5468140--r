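Package: windpellet
Title: Spatial Hierarchical Analysis of Pellet-Group Surveys Around Wind Farms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for before-after analysis of reindeer habitat use around wind-farm
    developments from fecal pellet-group counts. Implements the pellet-group counting
    and binning rules, point-transect and perimeter-square survey layouts, a binomial
    hierarchical generalized linear model with conditional-autoregressive (CAR) spatial
    random effects estimated by augmented iterative weighted least squares with
    quasi-likelihood dispersion, hierarchy-respecting backward model selection,
    a survey simulator emulating the Malaa wind-farm study design, and Monte Carlo
    power analysis for model terms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    glmmTMB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
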