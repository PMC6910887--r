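test_that("SNPSites validates alleles, depths and panel AF", {
    s <- SNPSites("chr1", 12345, "A", "G", 7, 8)
    expect_s4_class(s, "SNPSites")
    expect_equal(refDepth(s), 7L)
    expect_equal(altDepth(s), 8L)
    expect_true(is.na(panelAF(s)))

    expect_error(SNPSites("chr1", 1, "A", "GT", 1, 1), "single base")
    expect_error(SNPSites("chr1", 1, "A", "A", 1, 1), "differ")
    expect_error(SNPSites("chr1", 1, "A", "G", -1, 1), "non-negative")
    expect_error(SNPSites("chr1", 1, "A", "G", 1, 1, panelAF = 1.2),
                 "\\[0, 1\\]")
})

test_that("site tables round-trip and report malformed records by line", {
    f <- tempfile(fileext = ".tsv")
    s <- SNPSites(c("chr2", "chr2"), c(100L, 101L), c("C", "A"),
                  c("T", "G"), c(12L, 0L), c(11L, 0L),
                  panelAF = c(0.31, NA))
    writeSiteTable(s, f)
    r <- readSiteTable(f)
    expect_equal(start(r), start(s))
    expect_equal(refDepth(r), refDepth(s))
    expect_equal(panelAF(r), panelAF(s))
    # zero-depth sites are retained at parse time (filtered later)
    expect_equal(totalDepth(r)[2], 0L)

    # round trip is stable at the byte level after one cycle
    f2 <- tempfile(fileext = ".tsv")
    writeSiteTable(r, f2)
    expect_identical(readLines(f), readLines(f2))

    # header-only file -> empty set
    writeLines(readLines(f, n = 1L), f2)
    expect_length(readSiteTable(f2), 0L)

    # wrong header rejected
    writeLines(c("chrom\tpos", "chr1\t5"), f2)
    expect_error(readSiteTable(f2), "header")

    # negative depth names the line
    writeLines(c(readLines(f, n = 1L),
                 "chr1\t5\tA\tG\t-3\t4\t0.2"), f2)
    expect_error(readSiteTable(f2), "line 2")
})

test_that("VCF reader keeps biallelic SNVs and counts skips", {
    f <- tempfile(fileext = ".vcf")
    writeTinyVcf(f, records = c(
        vcfRecord("chr1", 123, "A", "G", "7,8"),
        vcfRecord("chr1", 200, "C", "T,G", "5,4,3"),   # multiallelic
        vcfRecord("chr1", 300, "G", "GA", "6,6"),       # indel
        vcfRecord("chr2", 150, "T", "C", "0,0")))       # zero depths kept
    s <- suppressMessages(readVcfSites(f, "S1"))
    expect_length(s, 2L)
    expect_equal(start(s), c(123L, 150L))
    expect_equal(refDepth(s), c(7L, 0L))
    expect_equal(altDepth(s), c(8L, 0L))
    skipped <- metadata(s)$skipped
    expect_equal(unname(skipped[["multiallelic"]]), 1L)
    expect_equal(unname(skipped[["not_snv"]]), 1L)
    expect_error(readVcfSites(f, "nope"), "not in VCF header")
    expect_error(readVcfSites(tempfile(), "S1"), "no such file")
})

test_that("panel files round-trip with sizes and gaps", {
    p <- tinyPanel()
    d <- tempfile()
    dir.create(d)
    writePanel(p, file.path(d, "p.tsv"),
               sizesPath = file.path(d, "sizes.tsv"),
               gapsPath = file.path(d, "gaps.bed"))
    p2 <- readPanel(file.path(d, "p.tsv"), file.path(d, "sizes.tsv"),
                    genome = "toy")
    expect_equal(length(p2), length(p))
    expect_equal(GenomeInfoDb::seqlengths(panelSites(p2)),
                 GenomeInfoDb::seqlengths(panelSites(p)))
    expect_equal(mcols(panelSites(p2))$af, mcols(panelSites(p))$af)
})

test_that("run-config files override defaults and reject unknown keys", {
    expect_equal(readRunConfig(NULL)$filter$minTotalDepth, 10L)
    f <- tempfile(fileext = ".yml")
    writeLines(c("filter:", "  minTotalDepth: 6", "  minPanelAF: 0.1",
                 "classify:", "  axisSlack: 0"), f)
    cfg <- readRunConfig(f)
    expect_equal(cfg$filter$minTotalDepth, 6L)
    expect_equal(cfg$filter$minPanelAF, 0.1)
    expect_equal(cfg$classify$axisSlack, 0)
    expect_equal(cfg$upd$minRun, 5L)           # untouched sections keep defaults
    writeLines(c("filter:", "  bogusKey: 1"), f)
    expect_error(readRunConfig(f), "bogusKey")
})

test_that("reports are deterministic and UPD BED is 0-based half-open", {
    counts <- countIntervals(c(0.30, 0.50, 0.66))
    call <- classifyPloidy(fitParabola(counts), ratioStatistic(counts),
                           counts, sampleId = "S1",
                           cfg = classifyConfig(minSites = 1L))
    upd <- GRanges("chr1", IRanges(1, 3e6),
                   kind = "segmental", nPinkBins = 3L,
                   fractionPink = 0.1)
    f1 <- tempfile(); f2 <- tempfile(); b <- tempfile()
    writeReport(call, f1, upd = upd, updPath = b,
                config = list(filter = filterConfig()))
    writeReport(call, f2)
    expect_identical(readLines(f1), c(readLines(f2),
        grep("^config\\.", readLines(f1), value = TRUE)))
    txt <- readLines(f1)
    expect_true(any(grepl("^verdict: ", txt)))
    expect_true(any(grepl("^n_candidate_sites: 3$", txt)))
    expect_true(any(grepl("^config\\.filter\\.minTotalDepth: 10$", txt)))

    bed <- readLines(b)
    expect_match(bed[1], "^#")
    expect_equal(strsplit(bed[2], "\t")[[1]][2:3], c("0", "3000000"))

    # empty UPD list -> header-comment-only BED
    writeUpdBed(GRanges(), b)
    expect_length(readLines(b), 1L)
})
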