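Package: rmrtools
Title: Residual Methylation Analysis for Germline Epigenetic Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window detection of residually methylated regions (RMRs)
    in globally demethylating primordial germ cell (PGC) methylomes, together
    with the surrounding analysis toolkit: readers for per-cytosine bisulfite
    call tables (methratio, Bismark coverage, bedGraph), CpG-dyad strand
    merging, feature-level methylation aggregation over transposable-element
    and CpG-island annotations, stage-resolved demethylation kinetics with
    erased/delayed/resistant classification, window-based differential
    methylation calling with exact tests and Benjamini-Hochberg correction,
    non-CpG (CH) context analysis including sequence-context frequency
    matrices and CpA-CpG coupling, region shuffling and signal metaprofiles
    for enrichment analysis, and a seeded simulator of stage- and
    genotype-resolved methylomes (wild type, full and mosaic knockouts) for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
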