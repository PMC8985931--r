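Package: fractalherd
Title: Fractal Electrode Geometry and Retinal Cell Herding Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and quantifying carbon-nanotube
    micro-electrodes that steer ("herd") retinal neurons onto textured
    electrode branches and glial cells into the smooth gaps between them.
    Builds vector and raster representations of H-tree fractal and Euclidean
    row electrode patterns, computes their geometric descriptors (edge
    length, tortuosity, distance-transform proximity, multi-scale gap
    areas), generates seeded synthetic two-channel fluorescence cultures
    with exact ground truth, measures neuronal process length and glial
    coverage per surface to form normalized herding indices, and compares
    groups of electrodes with Kruskal-Wallis and Dunn post-hoc statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
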