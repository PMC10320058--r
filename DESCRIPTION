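Package: gsora
Title: Configurable Gene Set Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds configurable gene-set collections from standard annotation
    sources (ontology files with ancestor propagation and evidence-code
    filters, GMT pathway and complex files, single-allele genotype-phenotype
    tables, tissue-preferential expression calls from RPKM matrices), maps
    heterogeneous gene identifiers onto a canonical id space, and tests one or
    many gene lists for over-representation against any collection using the
    hypergeometric upper tail with Bonferroni, Benjamini-Hochberg and
    Benjamini-Yekutieli adjustment. Emits result tables, cross-list comparison
    matrices, plot-data documents and bipartite gene/gene-set graphs, and
    ships a deterministic synthetic-fixture generator plus a command-line
    interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
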