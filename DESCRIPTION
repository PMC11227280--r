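Package: secisscan
Title: SECIS Element Discovery and Selenoprotein Gene Finding in Archaeal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structured-motif discovery of SECIS (selenocysteine insertion
    sequence) elements and selenoprotein genes in archaeal genome assemblies.
    Provides a PatScan-dialect pattern matcher with indel-tolerant stem
    back-references, structural models for eukaryotic-type (type I/II) and
    euryarchaeal-type SECIS elements, a fixed-structure nearest-neighbor
    free-energy evaluator with a -5.0 kcal/mol hairpin filter, Sec/TGA-pair
    selenoprotein gene calling with UGA read-through ORF extension, a
    Sec-utilization trait classifier, operon adjacency detection,
    motif-composition statistics, and a deterministic synthetic-genome
    generator with a planted-element truth ledger for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
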