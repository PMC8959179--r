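Package: mapscall
Title: Target Calling and Regulon Integration for MS2-Affinity
    Purification RNA-Seq (MAPS) of Bacterial Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies in-vivo targets of a bacterial small regulatory
    RNA from MS2-affinity purification coupled with RNA sequencing
    (MAPS) coverage data.  Builds a per-gene region model (5' UTR, gene
    body, 3' UTR) from a genome annotation and optional transcription
    start sites, computes strand-aware RPM-normalised region coverage,
    and calls candidate targets with a log2 fold-enrichment threshold
    plus a low-coverage quantile floor.  Companion tools test
    seed-pairing motif enrichment in candidate 5' UTRs with a one-sided
    exact binomial test, scan the genome with a transcription-factor
    position weight matrix and assign sites to promoters, select
    differentially expressed genes, average ChIP coverage over promoter
    windows, and fuse all evidence into a per-gene annotation matrix.
    A seeded synthetic-data generator emulates every input with known
    ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
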