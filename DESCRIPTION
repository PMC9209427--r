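Package: forestfire
Title: Forest Fire Clustering with Monte Carlo Label-Confidence Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based clustering for single-cell and other high-dimensional
    data by iterative label propagation on a K-nearest-neighbour affinity graph.
    Labels spread like a forest fire: a seed vertex is lit, heat (fire
    temperature times kernel affinity, averaged over the burning cluster) is
    compared against each vertex's acceptance threshold (the inverse of its
    weighted degree), and propagation stops where the data become sparse.
    Includes Monte Carlo internal validation producing per-point posterior label
    distributions, posterior exclusion probabilities and label entropies;
    inductive (online) assignment of newly arrived points with discovery of new
    clusters; seeded synthetic-data generators (Gaussian mixtures on the unit
    circle, 2-D shape benchmarks, Splatter-style scRNA-seq counts with
    differentiation paths); and clustering evaluation metrics (purity, adjusted
    Rand index, silhouette).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils,
    withr,
    jsonlite,
    RANN,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    uwot,
    optparse
Config/testthat/edition: 3
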