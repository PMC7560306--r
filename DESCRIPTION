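Package: shootgraph
Title: Skeleton-Graph Morphometry of Scanned Cereal Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated measurement of shoot traits from flatbed scans of
    dissected rice seedlings and coleoptiles laid on agar plates over a blue
    background. Plants are segmented by HSV colour thresholding (or Otsu
    grayscale thresholding for coleoptiles), reduced to one-pixel-wide
    skeletons, converted to graphs of terminal and branching nodes, pruned of
    short artifact spurs, and measured along geodesic paths: total shoot
    length, internode length, ordered leaf lengths and coleoptile length, all
    calibrated to millimetres through a scanned scale bar. Includes a
    deterministic synthetic-scene generator with exact per-organ ground truth,
    per-image and per-group summary statistics, and a program-versus-manual
    comparison report (Shapiro-Wilk, F and Student t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    igraph,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
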