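Package: chipRegulome
Title: ChIP-Seq and RNA-Seq Integration for Regulome Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of transcription-regulator ChIP-seq binding
    and knockdown RNA-seq responses. Provides consensus shortlisting of
    reproducibly deregulated genes and pathways across independent knockdown
    comparisons with transfection-control subtraction, Benjamini-Hochberg FDR
    handling and delta-delta-Ct fold-change conventions; summit-based peak
    annotation to fixed genomic features with TSS/TES-anchored metagene
    profiles; per-chromosome randomization overlap testing with Z-scores;
    signal-track cross-correlation and summit-centred conservation profiling;
    motif positional-enrichment summaries; and regulatory-potential regulome
    inference combining a binding distance-decay score with differential
    expression significance through a rank product, including
    Kolmogorov-Smirnov tests of activating versus repressive action. A fully
    parameterised synthetic-data generator (genomes, gene models of several
    classes, peak sets with tunable TSS bias, feature sets with planted
    overlap, correlated signal tracks, conservation bumps, and
    differential-expression tables with planted Venn structure) makes every
    stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
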