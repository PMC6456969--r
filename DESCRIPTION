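Package: chromrec
Title: Scalable 3D Chromatin Structure Reconstruction from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromatin structures from Hi-C
    contact maps. Contact frequencies are converted to spatial distances via a
    power-law model with the exponent estimated by golden-section search; a
    pivot-based shortest-path oracle serves approximate all-pairs distances in
    O(l*n + e) space; structures are assembled progressively by classical
    multidimensional scaling on overlapping random subsets merged through
    optimal rigid superposition with reflection handling, then polished by a
    scalable block-wise weighted MDS (SMACOF). Includes a confined random-walk
    polymer simulator with binary and Poisson contact-map observation models,
    and evaluation metrics (distance correlations, normalized RMSD,
    approximation ratio, exact matching rate).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
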