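Package: flowgwas
Title: Bayesian LASSO Genome-Wide Association and Genomic Prediction for
    Sire-Based Dairy Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker-effect estimation and interpretation for genome-wide
    association studies of progeny-tested sires, built around de-regressed
    breeding values as pseudo-phenotypes.  Fits all markers simultaneously by
    Bayesian LASSO regression (double-exponential prior on marker effects)
    with a pedigree-based polygenic effect, declares significance through
    within-chain permutation thresholds, cross-checks the null-marker
    proportion with a Bayes C-pi mixture sampler, collapses top markers into
    regions and annotates them against literature QTL intervals, and
    evaluates direct genomic values from nested marker subsets.  Includes a
    gene-dropping population simulator, marker quality control (call rate,
    minor allele frequency, Hardy-Weinberg), and Garrick-style de-regression
    of breeding values free of parent averages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    coda,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
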