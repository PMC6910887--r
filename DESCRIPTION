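Package: SNPloidy
Title: SNP-Based Triploidy and Uniparental Disomy Screening from
    Low-Coverage Whole-Genome Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies low-coverage whole-genome sequencing samples as
    diploid or triploid from the distribution of per-site alternate-allele
    read fractions (mutation ratios) at common heterozygous SNPs. Counts
    of candidate sites in the 1/3, 1/2 and 2/3 mutation-ratio intervals
    are interpolated exactly by a quadratic; the sign of its leading
    coefficient and the position of its symmetry axis give the ploidy
    verdict, with a within-batch Z test as auxiliary evidence. Also scans
    per-megabase heterozygous-SNP frequencies for whole-chromosome and
    segmental uniparental disomy, provides maternal-cell-contamination and
    depth-titration quality guards, a generative simulator of per-site
    allele depths, and confusion-matrix performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, SNP, Sequencing, QualityControl
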