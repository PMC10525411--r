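Package: invrisk
Title: Invasion Risk Assessment with Maximum-Entropy Distribution Models
    and Niche-Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing the invasion risk of an
    alien species: reconstruction of the invasion timeline from country
    first-record tables and its segmentation into lag, spread, and
    equilibrium phases; spatial thinning of occurrence records; reading,
    writing, and point-extraction of co-registered geographic raster
    layers; a presence-background maximum-entropy species distribution
    model with explicit feature classes (linear, quadratic, product,
    threshold, hinge), per-feature L1 regularization, AICc-based tuning
    over a regularization-multiplier grid, jackknife variable importance,
    permutation contributions, and response curves; niche-overlap and
    niche-dynamics statistics in a two-axis environmental space (Schoener's
    D, equivalency and similarity permutation tests,
    expansion/stability/unfilling); suitability thresholding with
    latitude-weighted, land-use-fraction-weighted area accounting, change
    maps, and latitudinal suitability profiles; and a seeded virtual-species
    simulator so the entire pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
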