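Package: netkmt
Title: Kernel Machine Tests of Association for Network Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semiparametric kernel machine score tests of association between
    the community structure of per-subject weighted networks (e.g. brain
    functional connectivity) and a binary or continuous outcome, adjusting
    for covariates. Pairwise similarity between subjects' community
    partitions is measured with extrinsic cluster evaluation metrics
    (two-way harmonic purity, normalized mutual information, adjusted Rand
    index) or an intrinsic metric (p-norm distance between optimized
    modularity or Potts Hamiltonian values), converted to a Gaussian
    distance kernel whose bandwidth, inestimable under the null, is handled
    by a grid search with a Davies upper bound on the score-test p-value.
    Includes Louvain and simulated-annealing spinglass community detection,
    a Beta-distribution simulator of weighted networks with planted
    communities, and a Monte Carlo harness for power and Type I error
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
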