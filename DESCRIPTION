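Package: fluxhr
Title: Uniform Hit-and-Run Sampling of Metabolic Flux Polytopes with
    Ellipsoid Rounding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Uniform sampling of the convex polytope of feasible metabolic
    steady states {v : S v = 0, vmin <= v <= vmax} by hit-and-run Markov
    chain Monte Carlo. Flux polytopes are heavily ill-conditioned because
    flux scales span many orders of magnitude; the package implements three
    rounding procedures that build an ellipsoid matching the polytope
    (principal component analysis of a pilot chain, iterative linear
    programming akin to flux variability analysis, and the Lovasz ellipsoid
    method yielding a weak Loewner-John pair) and uses it to bias the
    hit-and-run directions, which is equivalent to an affine rounding
    transformation and preserves uniformity. Also included: model readers
    (tabular and SBML/FBC), flux variability analysis and blocked-reaction
    removal, an artificially-centered hit-and-run baseline and a rejection
    sampling oracle, convergence diagnostics (integrated autocorrelation
    times by binning, Kolmogorov-Smirnov tests, histogram Kullback-Leibler
    divergence in bits), and seeded synthetic benchmark polytopes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
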