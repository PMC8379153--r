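Package: nanoruler
Title: DNA-Origami Nanoruler Analysis for Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying nanoscale structural preservation
    with DNA-origami nanorulers imaged by single-molecule localization microscopy
    (STORM). Localization tables are clustered into per-dye emitters with
    density-based clustering (DBSCAN) or, for closely spaced sites, K-means seeded
    by local maxima of a Gaussian-blurred image; emitters are grouped into origami
    objects, filtered by collinearity, and summarized as nearest-neighbor distance
    distributions whose first peak is fitted with a Gaussian. Comparing the fitted
    peak widths before and after hydrogel denaturation yields a per-emitter
    distortion estimate with its full-width-at-half-maximum equivalent. A synthetic
    field generator emulates linear and rectangular origami designs, dye blinking,
    incomplete labeling, gel distortion and isotropic expansion, so every stage of
    the pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
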