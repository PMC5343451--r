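Package: densmmi
Title: Multimodel Inference for Global Population-Density Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling the population density of a wide-ranging
    species across its global distribution from compiled site-level density
    estimates and landscape covariate rasters. Implements the full
    information-theoretic workflow: averaging of repeated density estimates,
    Welch comparison of island and mainland populations, proportional
    pseudo-absence (background) sampling in a buffer ring around the native
    range, moving-window (focal mean) covariate construction at multiple
    radii with AICc-based scale and form selection, Pearson-correlation
    pruning, all-subsets ordinary least squares regression ranked by AICc,
    Akaike weights and evidence ratios, full (zero-substitution) model
    averaging with unconditional standard errors, variable importance
    values, model-averaged prediction mapping with density classification,
    and k-fold cross-validation with mean squared prediction error using
    Huberty's rule of thumb to choose k. Includes a synthetic-landscape
    generator producing spatially autocorrelated covariate surfaces and
    density records with the statistical structure the analysis assumes,
    so the whole pipeline is testable without geospatial downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
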