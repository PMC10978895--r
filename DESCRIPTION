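Package: ceam
Title: Continuous Edge Angle Measurement for 3D-Scanned Bifacial Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic toolkit for analyzing the continuous edges of
    3D-scanned bifacial stone tools. Detects the closed 3D perimeter of an
    artifact from the alpha shape of its plan-view projection, measures the
    edge angle continuously at every perimeter coordinate (CEAM), segments
    the perimeter into discrete edges by optimal mean-shift change points
    with elbow model selection, and quantifies each segment's length,
    sharpness, transverse asymmetry, and surface concavity. Includes
    parametric shape generators (lenses, octahedra, blunt-banded forms) with
    closed-form ground truth for validation, plus batch processing and
    tabular export for whole assemblages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    sp,
    RANN,
    interp,
    igraph,
    jsonlite,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
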