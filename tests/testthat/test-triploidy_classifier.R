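test_that("mutation ratio is the alternate-read fraction", {
    s <- SNPSites(rep("chr1", 3), 1:3, "A", "G",
                  refDepth = c(5L, 20L, 4L), altDepth = c(5L, 10L, 8L))
    expect_equal(mutationRatio(s), c(0.5, 1 / 3, 2 / 3))
    z <- SNPSites("chr1", 9, "A", "G", 0L, 0L)
    expect_error(mutationRatio(z), "zero total depth")
})

test_that("interval counting uses closed disjoint intervals", {
    c1 <- countIntervals(c(0.30, 0.50, 0.66, 0.90))
    expect_equal(c(c1@nThird, c1@nHalf, c1@nTwoThirds, c1@nCandidates),
                 c(1L, 1L, 1L, 4L))
    # closed boundaries on every interval edge
    cb <- countIntervals(c(0.28, 0.38, 0.45, 0.55, 0.62, 0.72))
    expect_equal(c(cb@nThird, cb@nHalf, cb@nTwoThirds), c(2L, 2L, 2L))
    # MRs outside all intervals count only toward the candidate total
    c0 <- countIntervals(rep(0.40, 7))
    expect_equal(c(c0@nThird, c0@nHalf, c0@nTwoThirds, c0@nCandidates),
                 c(0L, 0L, 0L, 7L))
    expect_error(countIntervals(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(intervalConfig(half = c(0.30, 0.55)), "disjoint")
})

test_that("quadratic interpolation is exact and matches a least-squares
           oracle on random count triples", {
    set.seed(101)
    n <- 10000L
    triples <- matrix(rpois(3L * n, 40), ncol = 3L)
    triples <- triples[rowSums(triples) > 0, ]
    xs <- c(1 / 3, 1 / 2, 2 / 3)
    V <- cbind(1, xs, xs^2)          # Vandermonde solve: independent route
    maxResid <- 0
    maxCoefDiff <- 0
    for (i in seq_len(nrow(triples))) {
        fit <- fitParabola(triples[i, ])
        maxResid <- max(maxResid, abs(predictParabola(fit, xs) - fit@y))
        beta <- solve(V, fit@y)
        maxCoefDiff <- max(maxCoefDiff,
                           abs(c(fit@c, fit@b, fit@a) - beta))
    }
    # interpolation exactness at the three abscissae, and closed form ==
    # exact least squares, across all triples
    expect_lt(maxResid, 1e-12)
    expect_lt(maxCoefDiff, 1e-9)
    # spot-check the closed form against lm() as a second oracle
    for (tr in list(c(10, 20, 10), c(7, 3, 11), c(0, 5, 9))) {
        fit <- fitParabola(tr)
        co <- coef(lm(y ~ x + I(x^2), data.frame(x = xs, y = tr / sum(tr))))
        expect_equal(unname(co), c(fit@c, fit@b, fit@a), tolerance = 1e-9)
    }
})

test_that("ordinates sum to one, a-sign identity and symmetry hold", {
    set.seed(202)
    ok <- TRUE
    for (i in 1:200) {
        tr <- rpois(3, 15)
        if (sum(tr) == 0) next
        fit <- fitParabola(tr)
        ok <- ok && abs(sum(fit@y) - 1) < 1e-12 &&
            sign(fit@a) == sign(fit@y[1] + fit@y[3] - 2 * fit@y[2])
    }
    expect_true(ok)
    # symmetric side counts put the axis at exactly 0.5
    expect_identical(fitParabola(c(25, 50, 25))@axis, 0.5)
    expect_identical(fitParabola(c(7, 2, 7))@axis, 0.5)
    # symmetric diploid-like case: y = (.25, .5, .25) -> a = -9, axis .5
    f <- fitParabola(c(1, 2, 1))
    expect_equal(f@a, -9)
    expect_equal(f@axis, 0.5)
    # flat ordinates are the degenerate a = 0 case
    expect_equal(fitParabola(c(5, 5, 5))@a, 0)
    expect_true(fitParabola(c(0, 0, 0))@degenerate)
})

test_that("published per-sample coefficients are recovered from their
           side-to-centre ratios under sum normalisation", {
    # exact 2-d.p. round-trips
    expect_equal(round(countsWithRatio(2.16)@a, 2), 0.91)
    expect_equal(round(countsWithRatio(1.79)@a, 2), -1.35)
    # remaining reported rows agree within printed-rounding propagation
    rows <- list(c(2.29, 1.61), c(2.27, 1.47), c(2.24, 1.35),
                 c(2.26, 1.42), c(2.20, 1.14), c(2.21, 1.16),
                 c(2.24, 1.32), c(2.20, 1.13), c(1.80, -1.25),
                 c(1.76, -1.59), c(1.86, -0.90), c(1.90, -0.64),
                 c(1.83, -1.05))
    for (r in rows)
        expect_equal(countsWithRatio(r[1])@a, r[2], tolerance = 0.04)
})

test_that("ratio statistic of 2 is the exact sign boundary of a", {
    expect_equal(ratioStatistic(new("IntervalCounts", nThird = 10L,
                                    nHalf = 20L, nTwoThirds = 10L,
                                    nCandidates = 40L)), 1)
    # the analytic boundary: ratio 2 <=> y2 = 1/3 <=> a = 0
    expect_equal(fitParabola(c(10, 10, 10))@a, 0)
    set.seed(303)
    mismatches <- 0L
    for (i in 1:10000) {
        tr <- rpois(3, 12)
        if (tr[2] == 0 || sum(tr) == 0) next
        r <- (tr[1] + tr[3]) / tr[2]
        a <- fitParabola(tr)@a
        if (abs(a) < 1e-12) a <- 0    # snap float residue at the boundary
        if (sign(a) != sign(r - 2)) mismatches <- mismatches + 1L
    }
    expect_identical(mismatches, 0L)
    # undefined when the centre interval is empty
    expect_true(is.na(ratioStatistic(new("IntervalCounts", nThird = 5L,
                                         nHalf = 0L, nTwoThirds = 5L,
                                         nCandidates = 10L))))
})

test_that("batch Z standardises against a robust diploid reference", {
    # the reported batch reference: mean 1.77, sd 0.09
    z <- batchZ(c(1.77, 2.29, 1.80))$z
    expect_equal(z[1], (1.77 - mean(c(1.77, 1.8))) / sd(c(1.77, 1.8)))
    # direct formula on the published reference values
    expect_equal((2.29 - 1.77) / 0.09, 5.78, tolerance = 0.01)
    expect_equal((1.77 - 1.77) / 0.09, 0)

    ratios <- c(1.70, 1.80, 1.90, 2.29)
    bz <- batchZ(ratios, robust = TRUE)
    expect_equal(bz$stats@nReference, 3L)   # 2.29 excluded from reference
    expect_equal(bz$z, (ratios - 1.80) / 0.1)
    bzAll <- batchZ(ratios, robust = FALSE)
    expect_equal(bzAll$stats@nReference, 4L)

    expect_error(batchZ(c(1, 2)), "at least 3")
    expect_error(batchZ(c(2.3, 2.4, 2.5)), "reference samples")
    expect_warning(bz0 <- batchZ(c(1.8, 1.8, 1.8)), "SD is zero")
    expect_true(all(is.na(bz0$z)))
})

test_that("verdicts follow the opening direction and axis rule", {
    cfg <- classifyConfig(minSites = 10L)
    mk <- function(third, half, twoThirds) {
        cts <- new("IntervalCounts", nThird = as.integer(third),
                   nHalf = as.integer(half),
                   nTwoThirds = as.integer(twoThirds),
                   nCandidates = as.integer(third + half + twoThirds))
        classifyPloidy(fitParabola(cts), ratioStatistic(cts), cts,
                       cfg = cfg)
    }
    # upward opening, axis in range -> triploid (published positive row:
    # ratio 2.29, a 1.61, axis 0.55)
    tri <- mk(115, 100, 114)
    expect_gt(tri@fit@a, 0)
    expect_equal(verdict(tri), "triploid")
    # downward opening -> diploid (published negative row: 1.80, -1.25)
    expect_equal(verdict(mk(90, 100, 90)), "diploid")
    # upward but axis just beyond the bound: triploid, flagged (the
    # published 69,XXX with axis 0.56)
    skew <- mk(114, 100, 102)
    expect_gt(skew@fit@a, 0)
    expect_equal(round(skew@fit@axis, 2), 0.56)
    expect_equal(verdict(skew), "triploid")
    expect_true("axis_out_of_range" %in% qcFlags(skew))
    # under the strict rule the same counts are low-confidence
    cts <- skew@counts
    strict <- classifyPloidy(skew@fit, skew@ratio, cts,
                             cfg = classifyConfig(minSites = 10L,
                                                  axisSlack = 0))
    expect_equal(verdict(strict), "triploid_low_confidence")
    # axis far out of range -> low confidence even with slack
    far <- mk(300, 100, 10)
    expect_gt(far@fit@a, 0)
    expect_equal(verdict(far), "triploid_low_confidence")
    # a = 0 exactly -> inconclusive, never diploid
    flat <- mk(10, 10, 10)
    expect_equal(verdict(flat), "inconclusive")
    expect_true("degenerate_fit" %in% qcFlags(flat))
    # low candidate count -> inconclusive
    low <- classifyPloidy(fitParabola(c(3, 2, 3)), 3,
                          new("IntervalCounts", nThird = 3L, nHalf = 2L,
                              nTwoThirds = 3L, nCandidates = 8L),
                          cfg = classifyConfig(minSites = 1000L))
    expect_equal(verdict(low), "inconclusive")
    expect_true("low_sites" %in% qcFlags(low))
    # Z is auxiliary: an extreme Z flags but never flips a diploid verdict
    cts2 <- new("IntervalCounts", nThird = 90L, nHalf = 100L,
                nTwoThirds = 90L, nCandidates = 280L)
    zcall <- classifyPloidy(fitParabola(cts2), ratioStatistic(cts2), cts2,
                            z = 5.8, cfg = cfg)
    expect_equal(verdict(zcall), "diploid")
    expect_true("z_outlier" %in% qcFlags(zcall))
})

test_that("simulated diploids and triploids are classified correctly and
           batch calling attaches Z scores", {
    set.seed(1)
    b <- simulateBatch(4, 2, simConfig(nSitesPerChrom = 1200L), seed = 77)
    res <- callPloidyBatch(b$samples, b$panel,
                           classifyCfg = classifyConfig(minSites = 500L))
    tab <- res$table
    truthP <- b$truth$ploidy[match(tab$sampleId, b$truth$sampleId)]
    expect_equal(all(tab$verdict[truthP == "triploid"] %in%
                     c("triploid", "triploid_low_confidence")), TRUE)
    expect_equal(tab$verdict[truthP == "diploid"],
                 rep("diploid", 4))
    expect_s4_class(res$stats, "BatchStats")
    expect_true(all(is.finite(tab$z)))
    # triploids stand far from the diploid reference
    expect_true(all(tab$z[truthP == "triploid"] > 3))
})
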