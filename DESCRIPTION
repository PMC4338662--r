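Package: circuitboard
Title: Tissue Parcellation, Vascular Route Knowledge, and Drug Transport
    over Physiology Circuitboards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for multiscale computational physiology.
    Parcellates 3D labeled tissue volumes into primary functional tissue
    units (pFTUs) by true-Euclidean anisotropic dilation of advective
    channels and perpendicular segmentation along their centerlines;
    registers serial histology sections into 3D stacks by rigid
    sum-of-squared-differences matching with difference-profile outlier
    rescue; represents long-range vascular routes as a typed directed
    graph knowledgebase with ordered branching and microcirculation
    components; and simulates pulsatile blood flow (1D Navier-Stokes with
    a nonlinear pressure-area tube law closed by lumped-parameter RCR
    vascular beds) plus drug advection-diffusion coupled to receptor
    binding models gated by primary tissue motif (PTM) annotations.
    Includes seeded synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
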