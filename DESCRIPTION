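Package: circflow
Title: Back-Splice Junction Quantification and circRNA Biogenesis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying circular RNA (circRNA) biogenesis from
    RNA-seq-derived evidence: back-splice junction (BSJ) calling with
    canonical GT/AG splice-signal filtering, circular-to-linear junction
    ratios, saturation analysis, a conditional-binomial differential
    expression test with threshold-based circRNA classification, an intron
    database with flanking-intron assignment around collapsed circRNAs,
    exon-intron split analysis (EISA) of IP versus input libraries,
    cotranscriptional splicing efficiency from nascent RNA-seq windows,
    detection of reverse complementary matches (RCMs) in circRNA-flanking
    introns with repeat-overlap permutation testing, cross-link (iCLIP)
    enrichment statistics and metaprofiles, and positional motif enrichment
    at back-splice junctions. Includes a seeded synthetic-data generator
    that plants circRNAs, RCMs, motifs and cross-link enrichment so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
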