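#' X-chromosome-fraction contamination guard
#'
#' Maternal cells admixed into a fetal sample dilute the triploid
#' allele-fraction signal toward diploid values, so contaminated samples
#' risk false-negative calls. Because the contaminant is maternal (46,XX),
#' it shifts the sample's X-chromosome read share away from the value the
#' fetus' own sex predicts. This guard computes the depth-weighted fraction
#' of reads on the X chromosome, infers the apparent sex from the
#' X heterozygosity rate (XY samples show a near-zero X het rate relative to
#' autosomes), and flags possible contamination when the observed
#' X:autosome depth ratio is inconsistent — beyond the relative tolerance
#' \code{cfg$xTolerance} — with \emph{both} the pure-XX and the pure-XY
#' expectation derived from the panel's X share of covered sites. A male
#' fetus with female contamination sits between the two expectations and is
#' caught; a pure sample of either sex is not.
#'
#' @param sites a \linkS4class{SNPSites} object (unfiltered).
#' @param panel a \linkS4class{SNPPanel}.
#' @param filterCfg a [filterConfig()] (depth/panel filter before
#'   computing shares).
#' @param cfg a [qcConfig()].
#' @return a list (\code{QCSummary}): \code{xDepthFraction},
#'   \code{chromDepthFractions} (named, sums to 1),
#'   \code{xAutosomeDepthRatio}, \code{apparentSex} (\code{"XX"},
#'   \code{"XY"} or \code{"indeterminate"}), \code{expectedRatioXX},
#'   \code{expectedRatioXY}, \code{contaminationFlag} (logical, \code{NA}
#'   when indeterminate), \code{meanSiteDepth}.
#' @export
xFractionCheck <- function(sites, panel, filterCfg = filterConfig(),
                           cfg = qcConfig()) {
    # depth shares must not be conditioned on the analysis depth filter:
    # requiring >= minTotalDepth reads censors the lower-depth X sites of an
    # XY sample and drags the X:autosome ratio toward 1
    shareCfg <- filterCfg
    shareCfg$minTotalDepth <- 1L
    kept <- filterSites(sites, panel, shareCfg)
    chrom <- as.character(seqnames(kept))
    depth <- totalDepth(kept)
    byChrom <- tapply(as.numeric(depth), chrom, sum)
    fractions <- byChrom / sum(byChrom)

    if (!cfg$xChrom %in% names(fractions)) {
        warning("no covered sites on ", cfg$xChrom,
                "; contamination check indeterminate")
        return(list(xDepthFraction = NA_real_,
                    chromDepthFractions = fractions,
                    xAutosomeDepthRatio = NA_real_,
                    apparentSex = "indeterminate",
                    expectedRatioXX = NA_real_, expectedRatioXY = NA_real_,
                    contaminationFlag = NA,
                    meanSiteDepth = mean(depth)))
    }
    isX <- chrom == cfg$xChrom

    # apparent sex from the X heterozygosity rate
    het <- selectHeterozygous(kept, shareCfg)
    hetX <- sum(as.character(seqnames(het)) == cfg$xChrom)
    hetRateX <- hetX / max(sum(isX), 1L)
    hetRateAuto <- (length(het) - hetX) / max(sum(!isX), 1L)
    apparentSex <- if (hetRateAuto == 0) "indeterminate" else
        if (hetRateX / hetRateAuto < cfg$xHetRateRatio) "XY" else "XX"

    # per-site mean depth ratio X : autosome
    ratio <- mean(depth[isX]) / mean(depth[!isX])
    # expectations: XX has the autosomal dose on X, XY half of it
    expXX <- 1
    expXY <- 0.5

    consistentXX <- abs(ratio - expXX) <= cfg$xTolerance * expXX
    consistentXY <- abs(ratio - expXY) <= cfg$xTolerance * expXY
    flag <- if (apparentSex == "indeterminate") NA else
        !(consistentXX || consistentXY)

    list(xDepthFraction = unname(fractions[cfg$xChrom]),
         chromDepthFractions = fractions,
         xAutosomeDepthRatio = unname(ratio),
         apparentSex = apparentSex,
         expectedRatioXX = expXX, expectedRatioXY = expXY,
         contaminationFlag = flag,
         meanSiteDepth = mean(depth))
}

#' Depth-titration stability experiment
#'
#' Simulates replicate samples at each target mean depth, runs the
#' filtering/counting/ratio machinery, and summarises how the ratio
#' statistic behaves as depth falls — the data behind a depth-requirement
#' curve. Binomial read-sampling noise shrinks with depth, so the
#' dispersion of the ratio statistic is expected to be non-increasing in
#' depth and the curve to stabilise by roughly 3x.
#'
#' At depths of a few reads the usual 10-read total-depth filter would
#' discard nearly every site, so the titration accepts its own
#' \code{filterCfg} (default \code{minTotalDepth = 4}).
#'
#' @param cfg a [simConfig()] describing the sample to titrate (its
#'   \code{meanDepth} is overridden per depth).
#' @param depths numeric vector of target mean depths.
#' @param replicates simulation replicates per depth.
#' @param seed master seed; replicate seeds are derived from it.
#' @param filterCfg depth/panel filter used at all depths.
#' @param intervalCfg an [intervalConfig()].
#' @return \code{data.frame} with one row per depth: \code{depth},
#'   \code{meanRatio}, \code{sdRatio}, \code{cvRatio} (coefficient of
#'   variation \code{sdRatio/meanRatio} — the dispersion measure of the
#'   stability curve, since the mean itself shifts with depth),
#'   \code{nValid} (replicates with a defined ratio), and \code{z} — the
#'   mean ratio standardised against the replicate distribution at the
#'   deepest depth (the stable regime).
#' @export
depthTitration <- function(cfg = simConfig(), depths = c(1, 2, 3, 5, 10),
                           replicates = 50L, seed = 1L,
                           filterCfg = filterConfig(minTotalDepth = 4L),
                           intervalCfg = intervalConfig()) {
    stopifnot(all(depths > 0), replicates >= 1)
    panelCfg <- cfg
    panelCfg$seed <- as.integer(seed) + 700001L
    panel <- simulatePanel(panelCfg)
    ratios <- matrix(NA_real_, nrow = replicates, ncol = length(depths))
    for (d in seq_along(depths)) {
        for (r in seq_len(replicates)) {
            scfg <- cfg
            scfg$meanDepth <- depths[d]
            scfg$seed <- as.integer(seed) + 1000L * d + r
            sim <- simulateSample(scfg, panel = panel)
            kept <- selectHeterozygous(
                filterSites(sim$sites, panel, filterCfg), filterCfg)
            if (length(kept) == 0L) next
            ratios[r, d] <- ratioStatistic(countIntervals(kept,
                                                          intervalCfg))
        }
    }
    refCol <- ratios[, which.max(depths)]
    refMean <- mean(refCol, na.rm = TRUE)
    refSd <- stats::sd(refCol, na.rm = TRUE)
    m <- colMeans(ratios, na.rm = TRUE)
    s <- apply(ratios, 2, stats::sd, na.rm = TRUE)
    data.frame(
        depth = depths,
        meanRatio = m,
        sdRatio = s,
        cvRatio = s / m,
        nValid = colSums(!is.na(ratios)),
        z = (m - refMean) / refSd)
}
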