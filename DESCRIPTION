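Package: phycocomp
Title: Comparative Genomics of Genome Compaction in Green Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomic analysis of compact green-algal
    genomes, built around the question of whether a parasitic lifestyle is
    accompanied by metabolic reduction. Implements sequence-similarity-network
    gene-family analysis (reciprocal alignment edge criteria, connected
    components, contraction/expansion calls), pathway presence/absence
    retention profiling against reference gene sets, GH18 chitinase
    catalytic-motif scanning, assembly and gene-model compaction statistics
    (N50, GC, coding density, exon/intron geometry, coverage-based genome-size
    estimation), and reciprocal-best-hit synteny cluster detection. A
    synthetic-data module generates three-taxon proteomes and annotated toy
    genomes with a known truth ledger so the full pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
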