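Package: sweepscan
Title: Selective-Sweep Scans from Multi-Population Genotype Data
Version: 0.1.0
Authors@R:
    person("sweepscan", "developers", email = "sweepscan@example.org",
           role = c("aut", "cre"))
Description: Detects selective sweeps from multi-sample SNP genotype data in a
    three-population design (Target / Control / Background). Implements
    sliding-window Weir-Cockerham FST, the locus-specific branch length (LSBL),
    windowed nucleotide diversity, linkage-disequilibrium decay curves with
    half-maximum decay distance, empirical top-percentile outlier-region
    calling with gene overlap, haplotype-pattern extraction, coding-consequence
    annotation of SNPs, identity-by-state distances with neighbor-joining
    trees, and two seeded population-genetic simulators (Balding-Nichols and
    forward Wright-Fisher) so the whole pipeline is testable without external
    data. Reads VCF, GFF3 and FASTA; writes TSV, BED, VCF and newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
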