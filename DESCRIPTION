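Package: icrscan
Title: Genome-Wide Detection of Candidate Imprinting Control Regions from
    Clustered ZFP57 Binding-Site Composites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans chromosome sequences for the ZFP57 binding hexamer
    (TGCCGC) and for CpG-rich composite elements in which the hexamer
    overlaps an MLL1 morpheme ("ZFBS-morph overlaps"), computes a
    sliding-window density of composite-element occurrences that discards
    isolated sites, calls and classifies clusters of occurrences as
    candidate imprinting control regions (robust when a cluster holds
    three or more elements, weak at two), and exports UCSC genome browser
    custom tracks (BED and fixedStep wiggle) together with gene-proximity
    annotation of the called peaks. Includes a seeded synthetic-genome
    generator with planted motif clusters and ground truth so the whole
    pipeline is testable without assembly downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
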