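suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# tiny two-chromosome panel with hand-picked sites
tinyPanel <- function() {
    SNPPanel(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
             pos = c(100L, 200L, 300L, 150L, 250L),
             ref = c("A", "C", "G", "T", "A"),
             alt = c("G", "T", "A", "C", "C"),
             af = c(0.30, 0.04, 0.25, 0.50, 0.10),
             seqlengths = c(chr1 = 1000L, chr2 = 1000L),
             genome = "toy")
}

# counts with side-to-centre ratio r (2 d.p.), symmetric sides
countsWithRatio <- function(r, scale = 100L) {
    side <- as.integer(round(r * scale))
    s1 <- side %/% 2L
    fitParabola(c(s1, scale, side - s1))
}

# minimal VCF text with an AD FORMAT field
writeTinyVcf <- function(path, samples = "S1",
                         records = NULL) {
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=1000>",
             "##contig=<ID=chr2,length=1000>",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                    "Description=\"Allelic depths\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
    writeLines(c(hdr, records), path)
    path
}

vcfRecord <- function(chrom, pos, ref, alt, ad,
                      gt = "0/1", format = "GT:AD") {
    paste(chrom, pos, ".", ref, alt, "50", "PASS", ".", format,
          paste(gt, ad, sep = ":"), sep = "\t")
}

# a simulated sample cached once per test run
simFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateSample(simConfig(ploidy = "triploid",
                                               seed = 42,
                                               nSitesPerChrom = 1500L))
        cache
    }
})
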