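Package: holoquant
Title: Quantification of Nanoparticle Uptake from Holotomographic
    Refractive-Index Tomograms
Version: 0.1.0
Authors@R:
    person("holoquant", "maintainers", email = "holoquant@example.org",
           role = c("aut", "cre"))
Description: Label-free quantification of gold-doped nanoparticle uptake in
    cells from holotomographic 3D refractive-index (RI) tomograms. Provides
    RI-threshold cell delineation (background excluded below RI 1.34),
    detection of high-RI nanoparticle aggregates (RI exceeding 1.36) as 3D
    connected components, per-cell uptake metrics (aggregate count, volume
    fraction, mean RI), voxel-level colocalization between fluorescence and
    high-RI masks, correlation and group statistics, UV-Vis surface plasmon
    resonance calibration with direct and indirect gold loading-efficiency
    computations, and a synthetic tomogram generator with exact ground truth
    for end-to-end validation. Includes multi-page TIFF volume input/output
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    digest
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
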