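Package: bricomics
Title: Multi-Omics Differential Expression and Integration for Spaceflight
    Plant Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two-condition multi-omics experiments of the BRIC
    (Biological Research in Canisters) spaceflight design: negative-binomial
    likelihood-ratio differential expression for transcript counts, pooled
    t-tests for iTRAQ protein fractions and modified peptides, a decision
    rule that screens candidates against hardware and preservative control
    studies, hypergeometric overlap statistics for transcript/protein
    concordance, and Gene Ontology over-representation with depth-based
    term thinning.  A synthetic-data generator with known ground truth makes
    every stage testable without the original sequencing or mass-spectrometry
    runs, and curated summary tables from the BRIC-20 experiment (GLDS-38)
    ship as worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
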