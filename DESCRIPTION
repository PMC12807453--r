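Package: pausekit
Title: Quantification and Differential Analysis of RNA Polymerase II
    Promoter-Proximal Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing promoter-proximal pausing of RNA polymerase II
    from ChIP-seq fragment intervals. Quantifies strand-aware read densities in
    a window around the transcription start site (-300..+300 bp) and in the
    downstream region (+301..+1301 bp), selects occupied genes by a
    two-component Gaussian mixture cutoff on log10 TSS densities, computes
    per-gene pause release ratios (PRR = TSS density / downstream density),
    tests per-gene PRR changes between conditions with replicate t-tests and
    Benjamini-Hochberg correction, and summarises genome-wide pausing shifts.
    Includes the opposite-direction rescue-set logic for differential
    expression tables from a pause-release inhibitor experiment, and a seeded
    negative-binomial simulator that generates annotations, fragment files,
    count tables and DE tables with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ggplot2
Config/testthat/edition: 3
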