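Package: ccadeg
Title: Candidate-Gene Discovery from Canonical Correlations and Extreme-Score
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links multivariate phenotypes to environmental factors and to gene
    expression in ecological transcriptomics experiments. Implements canonical
    correlation analysis with canonical loadings, cross-loadings and the Wilks'
    lambda significance ladder (Rao's F approximation); selects extreme
    individuals on canonical scores to build paired differential-expression
    contrasts; tests genes with a negative-binomial exact test after TMM
    normalization and empirical-Bayes dispersion shrinkage; intersects the two
    DEG lists directionally into candidate genes; and annotates candidates by
    a conservative multi-species GO-term transfer rule followed by
    hypergeometric enrichment. Ships a synthetic-data generator that emulates a
    full-factorial rearing design (latitude x temperature x predator cue) with
    planted canonical correlations and planted expression shifts, so the whole
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    edgeR
Config/testthat/edition: 3
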