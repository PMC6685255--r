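Package: rloopann
Title: Expression-Aware Annotation of R-Loop DRIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates long, strand-ambiguous R-loop peaks from DRIP-seq
    experiments to genes and hence to DNA template strands, using gene
    expression to disambiguate peaks that overlap several genes. Each peak
    is decomposed into the gene features it covers (upstream flank, 5'UTR,
    exon, intron, 3'UTR, downstream flank), ambiguous placements are
    flagged, and per-feature enrichment is assessed against length-matched
    peaks shuffled genome-wide, with a chi-squared contingency test.
    Includes a seeded synthetic-genome fixture generator with recorded
    ground truth, summary tables and plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
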