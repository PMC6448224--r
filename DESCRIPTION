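Package: meristem3d
Title: Cellular Annotation and Morphometrics of 3D-Segmented Shoot Apical Meristems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates every cell of a 3D-segmented, dome-shaped shoot apical
    meristem. Cell layers (L1, L2, L3) are detected by iterative cone peeling
    against the tissue surface mesh, the organizing centre (stem-cell niche)
    is marked at a user-defined depth and radius beneath the apex, and each
    organ primordium with its boundary ring is delineated by a weighted
    Voronoi partition of cell centroids. Downstream morphometrics include
    cell volumes, PCA shape anisotropy, cell-adjacency networks and shared
    intercellular interface areas. A synthetic dome-phantom generator with
    known ground truth supports fully reproducible validation, and a
    command-line interface chains the pipeline on labeled TIFF volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
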