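Package: rwrscreen
Title: Network-Based Disease-Gene Prioritization by Random Walk with
    Restart and Screening Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by propagating a set of
    known (seed) genes over a weighted protein-protein interaction network
    with a random walk with restart, then filters the propagated hits
    through a three-stage screening cascade: an empirical permutation test
    on the propagation probabilities, a maximum-interaction-score test
    against the seed genes, and a maximum-enrichment-score test based on
    the cosine similarity of GO/KEGG annotation feature vectors. Reads
    STRING-style weighted edge lists, GMT gene-set files and OBO
    ontologies, and ships a stochastic-block-model fixture generator so
    the whole cascade is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
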