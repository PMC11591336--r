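Package: sweepscan
Title: Selective-Sweep Scans from SNP-Array Genotypes via Windowed F_ST and hapFLK
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects signatures of positive selection between groups of
    populations genotyped on medium-density SNP arrays. Implements the
    Weir-Cockerham unbiased fixation-index estimator with a one-SNP-step
    ("creeping") window smoother and empirical-percentile outlier calling,
    and the hapFLK haplotype-differentiation test built on a fastPHASE-style
    localized haplotype-cluster model fitted by EM together with a
    population kinship matrix derived from Reynolds distances and a
    midpoint-rooted neighbor-joining tree. Includes PLINK text/binary
    input-output, quality-control filters, KING-robust relatedness, genomic
    PCA, annotation of swept regions against gene/QTL intervals, and a
    Balding-Nichols founder-mosaic simulator of hierarchically structured
    populations with injectable sweeps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
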