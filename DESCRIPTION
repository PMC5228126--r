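Package: retgrad
Title: Retinal Ganglion Cell Density Gradients and Phylogenetic Comparative
    Analysis of Head and Eye Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate retinal configuration to head and eye movement
    behaviour across foveate bird species. Builds topographic maps of retinal
    ganglion cell density from stereology-style counting-frame samples,
    locates the fovea and expresses its position in normalized retinal
    coordinates, lays periphery-to-fovea transects along the four retinal
    axes and fits the linear density-gradient slopes used as the retinal
    configuration proxy, and regresses behavioural traits on those slopes
    with phylogenetic generalized least squares under Pagel's lambda
    (maximum-likelihood or REML estimation, boundary optima allowed).
    Includes a synthetic-data module generating wholemount retinas with a
    planted off-centre foveal peak, per-quadrant gradient steepness, Poisson
    counting noise, and Brownian-motion trait simulation on a phylogeny, so
    every stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
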