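Package: methkit
Title: Processing, Aggregation and Visualization of Nanopore Modified-Base Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A consolidated toolkit for per-read modified-base calls from
    nanopore sequencing. Imports calls from BAM files carrying SAM MM/ML base
    modification tags and from tabular caller outputs (megalodon, nanopolish,
    guppy, generic), normalizes scores to log likelihood ratios, classifies
    calls against adjustable two-sided cutoffs, aggregates them over segments,
    genome bins and motif sites (including haplotype-phased profiles and
    repeat-consensus composites), exports bedMethyl and DSS tables, and renders
    the corresponding score-distribution, segment, locus, region and composite
    plots. A synthetic-data generator with known per-site modification
    probabilities makes the whole chain testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    methods,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
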