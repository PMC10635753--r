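Package: bymap
Title: Bayesian Small-Area Disease Mapping with BYM Smoothing and Moran
    Cluster Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area analysis of registry count data: rook
    contiguity weights built directly from polygon geometry (GeoJSON in,
    GAL out), internally standardized incidence and mortality ratios,
    Besag-York-Mollie (BYM) hierarchical Poisson smoothing by
    Metropolis-within-Gibbs MCMC with credible-interval significance
    classification, Geweke convergence diagnostics, and global and local
    Moran's I cluster detection with Monte-Carlo permutation inference.
    Includes a synthetic registry and geography generator so every
    pipeline stage can be exercised without restricted cancer-registry
    data, plus a command-line driver and choropleth export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
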