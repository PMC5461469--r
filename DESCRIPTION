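Package: oraltox
Title: Acute Oral Toxicity Dossier Analysis and Similarity-Informed
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of tabulated regulatory oral-toxicity
    dossiers: substance-level aggregation of LD50 and NOAEL endpoints,
    inter-guideline concordance, contingency analyses of acute versus
    repeated-dose redundancy rules (28-day NOAEL thresholds, 90-day
    predictivity, factor-3 derived no-effect levels), Tanimoto similarity
    graphs with modularity-based module detection, a similarity-constrained
    k-nearest-neighbour toxicant classifier fused into supervised learners
    (weighted decision tree and multilayer perceptron), information-gain and
    wrapper feature-importance protocols over balanced sub-datasets, and a
    synthetic dossier generator that reproduces the statistical structure of
    public registration data so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    rpart,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
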