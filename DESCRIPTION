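Package: retroquartet
Title: Quartet-Based Coalescent Analysis of Retroelement Insertion Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-tree inference and support analysis for retroelement
    insertion (RI) presence/absence matrices under the multispecies
    coalescent. Each RI character is treated as a single-bipartition gene
    tree; species trees are scored and searched by quartet agreement
    (optionally weighted and combined with sequence-based gene trees),
    internal branches are annotated with coalescent-unit lengths and
    Bayesian local posterior probabilities, and clade stability is
    quantified by character bootstrap, partitioned coalescence support,
    locus-removal indices, and linked-support reports. Unordered parsimony
    mapping identifies perfectly congruent synapomorphies, emergent clades,
    and hidden synapomorphies; quartet-asymmetry binomial tests and a
    triplet likelihood-ratio test detect introgression. A coalescent
    simulator generates RI matrices and support-labeled gene trees on
    species trees or one-reticulation networks with missing-data masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
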