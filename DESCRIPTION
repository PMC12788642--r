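Package: igtdx
Title: Tabular-to-Image Conversion with Non-Euclidean Feature Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts numeric feature tables (samples by features) into
    grayscale pseudo-images for convolutional neural network classification,
    following the IGTD rank-matching scheme: pairwise feature dissimilarities
    are ranked, pixel distances on a target grid are ranked, and features are
    assigned to pixels by iteratively swapping pairs to minimise the squared
    difference between the two rank matrices. Beyond the Euclidean baseline,
    five feature dissimilarities are provided: one minus Pearson correlation,
    geodesic distance along a k-nearest-neighbour feature graph, Jensen-Shannon
    divergence between per-feature probability mass functions, the
    one-dimensional quantile form of the Wasserstein distance, and the tropical
    (max-plus) distance. The package bundles six metric-aligned simulation
    generators, a compact two-block convolutional network with repeated
    stratified cross-validation for evaluating pseudo-image classifiability,
    and plotting/reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
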