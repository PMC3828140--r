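Package: parasitome
Title: Genome Architecture and Infection Transcriptomics of Nematode-Trapping Fungi
Version: 0.9.0
Authors@R:
    person("Parasitome", "Maintainers", email = "maintainers@parasitome.org",
           role = c("aut", "cre"))
Description: Tools for analysing the genome architecture and infection
    transcriptome of nematode-trapping fungi and related filamentous
    ascomycetes. Implements repeat-induced point mutation (RIP) dinucleotide
    indices and RIP-affected gene calling, stop-codon bias statistics,
    tandem gene duplication detection with a gene-order permutation test,
    transposable-element proximity annotation, recent-duplicate screening by
    global pairwise alignment, secreted-protein gene-cluster detection,
    small secreted protein (SSP) classification, count normalisation with
    fold-change regulation sets and hypergeometric enrichment, cross-species
    ortholog expression comparison, and a seeded synthetic-genome and
    expression simulator with plantable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
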