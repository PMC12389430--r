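Package: standstruct
Title: Stand Spatial and Non-Spatial Structure Analysis from Backpack
    Laser Scanning Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying forest stand structure from mobile
    (backpack) laser-scanning point clouds or conventional tree tables,
    developed around mixed, multi-storied natural stands such as ancient
    tea-tree (Camellia taliensis) communities. Covers point-cloud
    pre-processing (plot clipping, random thinning, statistical outlier
    removal, ground classification, TIN elevation model and height
    normalization), individual-tree parameter extraction (trunk detection,
    least-squares circle fitting of breast-height slices for DBH, tree
    height, stem-base coordinates), nearest-neighbour spatial structure
    indices (uniform angle, mingling, dominance, Hegyi competition) with
    edge-buffer correction and Voronoi adjacency, non-spatial structure
    (Patrick, Margalef, Shannon-Wiener, Simpson, Pielou, importance values,
    diameter-class distributions), accuracy evaluation of scanner-derived
    against field measurements, and seed-reproducible synthetic stand and
    stem-cloud generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
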