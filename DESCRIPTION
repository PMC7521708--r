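Package: essnet
Title: Essential Gene Prediction from Sequence Features and Network Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene essentiality by combining codon-usage features derived
    from coding and protein sequences (codon frequencies, relative synonymous
    codon usage, codon adaptation index, GC content, lengths, amino-acid
    frequencies) with 64-dimensional node embeddings learned from a
    protein-protein interaction network via biased random walks and a
    skip-gram model. A cost-sensitive multilayer perceptron handles the
    strong class imbalance typical of essentiality screens, and the package
    ships the full imbalanced-learning evaluation protocol (repeated
    stratified holdouts with negative downsampling, ROC-AUC, average
    precision, sensitivity/specificity/PPV/accuracy), centrality baselines,
    and a seeded synthetic-cohort generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
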