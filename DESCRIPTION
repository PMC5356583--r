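Package: imbnet
Title: Integrative Molecular Bayesian Networks from Expression and Copy Number Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs integrative molecular Bayesian networks (IMBNs) from
    discretized gene expression with copy-number-derived cis-regulatory priors,
    and provides the downstream analytics used to interrogate them: consensus
    averaging over annealing restarts, network accuracy against reference edge
    and gene-set collections with permutation nulls, signature ROC curves with
    partial AUC, key-regulator and distinct-key-driver calls, shortest-path
    common-mediator ranking, Cox screening of genes against a recurrence
    endpoint, gene-low survival stratification against a normal-tissue
    reference, and tissue preferential-expression tallies. A synthetic-data
    module generates ground-truth causal networks with coupled copy-number,
    expression, survival and tissue-atlas data so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    survival,
    fgsea,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
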