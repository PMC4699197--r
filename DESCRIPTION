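Package: octlayers
Title: Graph-Based Retinal Layer Segmentation and Enface Mapping for SDOCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated segmentation of five retinal cell-layer interfaces
    in spectral-domain optical coherence tomography (SDOCT) B-scans using
    gradient-derived graph weights and a shortest-path (dynamic programming)
    boundary search, with an ordered five-interface protocol, search-region
    restriction, and band-restricted manual correction. Downstream products
    include enface thickness maps and reflectance images of the total retina,
    inner retina, outer retina and inner segment ellipsoid band, per-pixel
    normative atlases (mean, SD, normal-range limits) built from control
    cohorts, and tri-level deviation maps. A deterministic synthetic SDOCT
    phantom generator with exported ground-truth boundaries and diabetic
    retinopathy pathology injectors supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
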