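Package: optodesign
Title: Automated Optimized Array Design for Functional Near-Infrared
    Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs source-detector optode layouts for functional
    near-infrared spectroscopy (fNIRS). Builds extended 10-20 scalp
    positioning systems (10-10, 10-5, 10-2.5) on a triangulated scalp
    surface, assembles channel sensitivity distributions (photon
    measurement density functions) on the cortical surface from
    pluggable fluence providers, applies a signal-to-noise weighting of
    channel separation, and maximizes a combined normalized-sensitivity
    plus region-of-interest coverage objective with a greedy randomized
    adaptive search procedure (GRASP). Includes an exhaustive exact
    solver for small instances, a manual single-distance array baseline,
    a synthetic head generator for testing, and a benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
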