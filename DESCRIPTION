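Package: amyloidscope
Title: Quantification of Beta-Amyloid Plaques in Light-Sheet Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for beta-amyloid plaque
    burden in cleared-brain light-sheet (ultramicroscopy) volumes. Generates
    seeded synthetic 3D stacks with planted quasi-spherical plaques, vessel and
    stripe artifacts, depth attenuation, Rayleigh-range-dependent axial blur and
    camera noise, together with exact ground truth; segments plaques by
    thresholding and 3D connected components with shape-based artifact
    exclusion and an 8 micrometre counting floor; and summarises plaque counts
    per cubic millimetre, plaque load (volume percent) and equivalent-sphere
    diameter distributions over cortex-normalised sample cubes, with
    nonparametric group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
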