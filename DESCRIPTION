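Package: domarch
Title: Consolidation and Analysis of Protein Domain Architectures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-database protein domain annotations (Pfam, CDD, SMART,
    SUPERFAMILY and the other InterPro member databases) are redundant: a
    single region is typically reported several times under different names
    and slightly different boundaries. 'domarch' consolidates such
    annotations into exactly one curated domain call per region using an
    iterative overlap-resolution algorithm with a configurable overlap
    threshold, size window and database preference; enumerates the distinct
    domain architectures of a protein family with their prevalence;
    attributes additional sequences to architectures by best-hit global
    identity; builds a domain co-occurrence network; writes annotation
    files for the Interactive Tree of Life (iTOL); and compares the
    evolution of individual excised domains with Kruskal-Wallis and Dunn
    post hoc statistics. Results persist in a three-table SQLite store. A
    seeded synthetic-fixture generator with known ground truth makes every
    step testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    RSQLite,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
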