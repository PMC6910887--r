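test_that("bins partition each chromosome exactly once", {
    sim <- simFixture()
    bins <- binHSF(sim$sites, sim$panel)
    for (chr in GenomeInfoDb::seqlevels(bins)) {
        b <- bins[seqnames(bins) == chr]
        expect_equal(start(b)[1], 1L)
        expect_equal(end(b)[length(b)],
                     GenomeInfoDb::seqlengths(bins)[[chr]])
        expect_true(all(start(b)[-1] == end(b)[-length(b)] + 1L))
    }
    expect_true(all(mcols(bins)$nHet <= mcols(bins)$nInformative))
})

test_that("bin colours follow the HSF, informativeness and gap rules", {
    # hand-built sites on a 3-Mb chromosome, depth 30 everywhere
    mkSites <- function(chrom, pos, het) {
        SNPSites(chrom, pos, "A", "G",
                 refDepth = ifelse(het, 15L, 30L),
                 altDepth = ifelse(het, 15L, 0L))
    }
    pos1 <- seq(1000L, 999000L, length.out = 100L)       # bin 1
    pos2 <- seq(1000001L, 1999000L, length.out = 100L)   # bin 2
    pos3 <- seq(2000001L, 2999000L, length.out = 5L)     # bin 3: sparse
    het <- c(rep(c(TRUE, rep(FALSE, 49)), 2),            # bin 1: 2/100
             rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 20), # bin 2: 60/100
             rep(FALSE, 5))
    pos <- as.integer(c(pos1, pos2, pos3))
    s <- mkSites("chr1", pos, het)
    panel <- SNPPanel(rep("chr1", length(pos)), pos, "A", "G",
                      af = rep(0.4, length(pos)),
                      seqlengths = c(chr1 = 3000000L))
    bins <- binHSF(s, panel)
    expect_equal(mcols(bins)$color, c("pink", "green", "yellow"))
    expect_equal(mcols(bins)$hsf, c(0.02, 0.60, NA))
    expect_equal(mcols(bins)$nInformative, c(100L, 100L, 5L))

    # a declared gap covering most of bin 2 overrides its colour
    panelG <- SNPPanel(rep("chr1", length(pos)), pos, "A", "G",
                       af = rep(0.4, length(pos)),
                       seqlengths = c(chr1 = 3000000L),
                       gaps = GRanges("chr1",
                                      IRanges(1100001L, 1900000L)))
    binsG <- binHSF(s, panelG)
    expect_equal(mcols(binsG)$color[2], "gap")
    expect_true(is.na(mcols(binsG)$hsf[2]))

    expect_error(binHSF(mkSites("chrZ", 10L, TRUE), panel), "chrZ")
})

test_that("whole-chromosome and segmental calls come from pink runs", {
    colorBins <- function(colors, chr = "chr1") {
        n <- length(colors)
        b <- GenomicRanges::tileGenome(
            setNames(n * 1000000L, chr), tilewidth = 1000000L,
            cut.last.tile.in.chrom = TRUE)
        mcols(b) <- S4Vectors::DataFrame(
            nHet = 0L, nInformative = 50L,
            hsf = ifelse(colors == "pink", 0.01,
                  ifelse(colors == "green", 0.3, NA)),
            color = colors)
        b
    }
    # all informative bins pink -> one whole-chromosome call
    calls <- callUPD(colorBins(rep("pink", 30)))
    expect_equal(mcols(calls)$kind, "whole_chromosome")
    expect_equal(start(calls), 1L)
    expect_equal(end(calls), 30000000L)

    # a 12-bin pink run inside a green chromosome -> one segmental call
    colors <- c(rep("green", 10), rep("pink", 12), rep("green", 8))
    calls <- callUPD(colorBins(colors))
    expect_equal(mcols(calls)$kind, "segmental")
    expect_equal(start(calls), 10000001L)
    expect_equal(end(calls), 22000000L)
    expect_equal(mcols(calls)$nPinkBins, 12L)

    # isolated pink bins below the run minimum -> no call
    scattered <- rep("green", 30)
    scattered[c(3, 9, 17, 25)] <- "pink"
    expect_length(callUPD(colorBins(scattered)), 0L)

    # one yellow interruption is tolerated inside a run; two are not
    oneGap <- c(rep("green", 5), rep("pink", 3), "yellow", rep("pink", 3),
                rep("green", 5))
    calls <- callUPD(colorBins(oneGap))
    expect_equal(mcols(calls)$kind, "segmental")
    expect_equal(mcols(calls)$nPinkBins, 6L)
    # a second interruption ends the run: neither fragment reaches 5 pinks
    twoGaps <- c(rep("green", 4), rep("pink", 3), "yellow", "pink",
                 "yellow", rep("pink", 3), rep("green", 4))
    expect_length(callUPD(colorBins(twoGaps)), 0L)
})

test_that("a simulated isodisomic chromosome is recovered and calls are
           order-invariant", {
    upd <- GRanges("chr2", IRanges(1, 1e8))
    cfg <- simConfig(seed = 314, updRegions = upd)
    sim <- simulateSample(cfg)
    bins <- binHSF(sim$sites, sim$panel)
    calls <- callUPD(bins)
    whole <- calls[mcols(calls)$kind == "whole_chromosome"]
    expect_equal(as.character(seqnames(whole)), "chr2")

    shuf <- sim$sites[sample(length(sim$sites))]
    expect_equal(callUPD(binHSF(shuf, sim$panel)), calls)

    # truth region recovered with >= 90% bin-level overlap
    expect_gte(sum(width(GenomicRanges::intersect(calls, upd))) /
               sum(width(upd)), 0.9)
})
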