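Package: thermoreg
Title: Non-Equilibrium Thermodynamics and Regulatory Network Analysis of
    Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled metabolic/transcriptional analysis of expression
    cohorts: a non-equilibrium thermodynamic model of transcription
    (intensity-dependent mRNA concentration via a two-state competitive
    hybridization isotherm, transcriptional affinity, and chemical
    potential per gene), nonlinear-correlation regulatory-network
    inference with the Information Based Similarity (IBS) distance around
    a data-mined core set of master-regulator transcription factors,
    two-group moderated differential expression, and pathway/gene-set
    enrichment (hypergeometric over-representation and GSEA with
    phenotype permutations). A synthetic-data generator with a recorded
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
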