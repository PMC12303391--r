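Package: pringle
Title: Projection and Neighborhood Analysis of Cell Identity in Curved Epithelia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying three-dimensional patterning of cell
    identity in curved epithelial sheets from segmented-nuclei data.
    Implements projection of curved epithelia onto landmark-normalized 2D
    maps via principal curves (PRINGLE), normalized fluorescence intensity
    (NFI) with bleed-through unmixing and depth-attenuation correction,
    Delaunay neighbor graphs with iterative kernel smoothing, per-nucleus
    neighborhood statistics (gradient steepness, coefficient of variation,
    log neighbor ratio against a per-niche synthetic null, 1D earth mover's
    distance), a pseudospace cell-state axis from PCA plus a principal
    curve with region-of-interest gating, k-means spatial binning with
    per-bin condition tests, semi-supervised epiblast classification, and a
    seeded synthetic-embryo generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SingleCell, Spatial, CellBiology
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'NucleiSet-methods.R'
    'RcppExports.R'
    'classify.R'
    'compare.R'
    'io.R'
    'utils.R'
    'neighbors.R'
    'metrics.R'
    'normalize.R'
    'synthgen.R'
    'principal-curve.R'
    'pseudospace.R'
    'pringle.R'
    'pipeline.R'
    'quantify.R'
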