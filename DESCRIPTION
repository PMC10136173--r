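Package: contourGraph
Title: Seeded Breast-Contour Detection by Shortest Paths on Learned Edge
    Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic detection of breast contours in frontal torso
    photographs for the assessment of aesthetic outcomes of breast cancer
    conservative treatment. An edge map (Sobel, Prewitt, Canny or a
    learned Sobel-skip U-Net) is converted into a weighted 8-connected
    pixel graph with exponential edge-strength arc weights, and the
    contour between two annotated endpoints is extracted as the
    minimum-cost path by Dijkstra's algorithm, optionally biased by an
    endpoint-conditioned shape-prior mask. The learned edge detector is
    trained with a structured hinge loss that penalises edge maps under
    which the annotated ground-truth contour is costlier than the current
    shortest path. Includes a synthetic torso-scene generator with known
    ground-truth contours, a contour-distance evaluation harness with
    k-fold splitting, and annotation/configuration I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    tools,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
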