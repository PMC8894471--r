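Package: captss
Title: Transcription Start Site Calling and Xenogeneic Silencer Occupancy
    Analysis from Cappable-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of bacterial transcription start sites
    (TSSs) and xenogeneic-silencer occupancy from cappable-seq 5'-end
    coverage. Calls TSSs with a replicate-consistent threefold step rule,
    annotates promoter -10 elements with spacer and discriminator
    properties, builds TSS-anchored sequence-logo matrices and initiating
    nucleotide usage tables, classifies TSSs by genomic context (coding
    versus non-coding, silencer-bound versus free), quantifies
    nucleoid-associated protein binding shape via 10-bp binning,
    start-codon-anchored aggregate profiles and percent-of-max signal
    curves, and tests differential transcript and TSS activity between two
    conditions with an exact conditional rate test and Benjamini-Hochberg
    FDR control. A seeded synthetic-data generator emulates AT-rich
    islands, planted promoters, narrow (Rok-like) and broad (H-NS-like)
    silencer occupancy, and overdispersed replicate coverage so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
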