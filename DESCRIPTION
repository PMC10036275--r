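Package: crownscorch
Title: Individual-Tree Crown Scorch Assessment from Drone Photogrammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses post-fire severity of individual conifer trees from
    photogrammetric (RGB drone) data. Segments tree crowns from a canopy height
    model with a marker-controlled watershed, classifies each crown as burned or
    unburned from the Green Leaf Index of orthomosaic pixels, and estimates crown
    scorch height, crown base height, and crown volume scorched from vertical
    spectral and point-density profiles of the colored point cloud. Includes a
    synthetic scene generator that emulates drone acquisitions over mixed
    burned/unburned plots with known ground truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
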