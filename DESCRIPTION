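Package: thermoherb
Title: Statistical Analysis of Hot and Cold Herb Properties
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes herb temperament annotations from two property
    databases onto a nine-level ordinal scale, identifies property-specific
    ingredients and target genes by hypergeometric over-representation with
    Benjamini-Hochberg correction and a dual-comparison specificity rule,
    maps specific targets to pathways and an enrichment-map style similarity
    network, and contrasts transcriptomic signatures of hot- versus
    cold-enriched components with preranked gene set enrichment analysis.
    Includes a synthetic-data generator with planted, parameterized signal so
    every pipeline stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
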