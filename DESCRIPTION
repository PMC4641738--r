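Package: metacog
Title: COG Functional Annotation of Metagenomic Reads with Directed
    Search and Cross-Database Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates nucleotide reads from metagenomes and
    metatranscriptomes with COG (Clusters of Orthologous Groups)
    functional categories via translated (six-frame) protein homology
    search, either in a single pass against a full tagged reference
    database or with a two-stage directed search through a clustered,
    reduced representative database. A cross-mapping store derives KEGG,
    Pfam, GO and SEED annotations from each COG call without further
    alignment. Includes a built-in Smith-Waterman search engine with
    Karlin-Altschul e-values, an adapter for external aligner hit tables,
    a synthetic fixture generator with known read provenance, and a
    PPV/NPV benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
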