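Package: CombQuant
Title: Quantification of Capped Brood and Honey on Hive Frame Photographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automated measurement of capped brood and capped honey
    surface on photographs of honey-bee hive frames. Uncapped cells are
    detected as dark circular lumens with a Hough gradient transform on the
    CIELAB lightness channel; their aggregate area is subtracted from
    operator-outlined capped regions, and pixel areas are calibrated to
    physical units through the inner-frame quadrilateral. Includes a seeded
    synthetic comb-image generator with analytic ground truth, mass
    estimators for food stores, an exact paired signed-rank test for
    small-sample method comparisons, and a batch command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImageAnalysis, CellBasedAssays, Software
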