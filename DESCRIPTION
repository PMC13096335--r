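Package: cutmap
Title: Mapping Endonuclease Cleavage Sites from Read 5' Ends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls endonuclease cleavage-site peaks from the 5' ends of
    aligned sequencing reads (SITE-seq style experiments), with CPM
    normalization, moving-average smoothing, log2 fold-change tracks,
    raw-count replicate consistency and summit merging. Also prepares
    fixed-width summit windows for motif discovery and scans sequences for
    IUPAC-degenerate motifs, computes gene-neighborhood tRNA-density
    enrichment statistics (one-sided paired Wilcoxon signed-rank test and a
    bootstrap confidence interval for the median difference), and maps
    condition-dependent tRNA cleavage positions from tRNA-fragment
    sequencing coverage ratios. A synthetic-data generator with planted
    ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    methods,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
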