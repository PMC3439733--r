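Package: genesetnet
Title: Gene-Set Similarity, Enrichment Search and Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for analysing gene-set collections: weighted
    Jaccard/cover-coefficient similarity scoring between gene sets,
    over-representation search of query gene lists with one-sided Fisher's
    exact tests and Benjamini-Hochberg false discovery control,
    differential gene-set expression via a normalised p-norm of absolute
    fold changes (NORM_ABS_FC), construction and export of gene-set
    association networks (GSAN) for Cytoscape, gene-set scale-distribution
    statistics with log-log regression, and a seeded synthetic-data
    generator producing collections with controlled overlap structure and
    expression tables with planted differential signal. Reads and writes
    GMT, tabular membership, gene-list and delimited expression formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
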