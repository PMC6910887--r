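#' Configuration constructors
#'
#' Each analysis stage takes a small validated configuration list. All
#' thresholds can also be supplied through a single plain-text config file
#' (see [readRunConfig()]); every run can log the resolved configuration via
#' [writeReport()].
#'
#' @name configs
NULL

#' Site-filtering configuration
#'
#' Candidate SNPs for ploidy analysis must be present in the common-SNP
#' panel, have a population alternate-allele frequency above
#' \code{minPanelAF}, and carry at least \code{minTotalDepth} reads in total.
#' Heterozygosity is defined observationally: both alleles supported by at
#' least \code{hetMinMinorReads} reads (the diploid-model genotype call in a
#' VCF is ignored, since it is unreliable for triploids).
#'
#' @param minPanelAF minimum population AF (exclusive), default 0.05.
#' @param minTotalDepth minimum total read depth (inclusive), default 10.
#' @param requirePanel must sites match the panel? default \code{TRUE}.
#' @param hetMinMinorReads minimum reads on each allele for a site to count
#'   as heterozygous, default 1.
#' @return a list of class \code{FilterConfig}.
#' @examples
#' filterConfig(minTotalDepth = 8)
#' @export
filterConfig <- function(minPanelAF = 0.05, minTotalDepth = 10L,
                         requirePanel = TRUE, hetMinMinorReads = 1L) {
    stopifnot(minPanelAF >= 0, minPanelAF <= 0.5, minTotalDepth >= 1,
              hetMinMinorReads >= 1)
    structure(list(minPanelAF = minPanelAF,
                   minTotalDepth = as.integer(minTotalDepth),
                   requirePanel = isTRUE(requirePanel),
                   hetMinMinorReads = as.integer(hetMinMinorReads)),
              class = "FilterConfig")
}

#' Mutation-ratio interval configuration
#'
#' The three closed MR intervals in which candidate heterozygous sites are
#' counted: the 1/3 interval \eqn{[0.28, 0.38]}, the 1/2 interval
#' \eqn{[0.45, 0.55]} and the 2/3 interval \eqn{[0.62, 0.72]}. They must be
#' pairwise disjoint and inside \eqn{(0, 1)}.
#'
#' @param third,half,twoThirds numeric(2) closed intervals.
#' @return a list of class \code{IntervalConfig}.
#' @export
intervalConfig <- function(third = c(0.28, 0.38), half = c(0.45, 0.55),
                           twoThirds = c(0.62, 0.72)) {
    iv <- list(third = third, half = half, twoThirds = twoThirds)
    for (v in iv)
        stopifnot(length(v) == 2L, v[1] < v[2], v[1] > 0, v[2] < 1)
    o <- rbind(iv$third, iv$half, iv$twoThirds)
    o <- o[order(o[, 1]), ]
    if (any(o[-1, 1] <= o[-3, 2]))
        stop("MR intervals must be pairwise disjoint")
    structure(iv, class = "IntervalConfig")
}

#' Classification configuration
#'
#' Verdict rules for [classifyPloidy()]: a sample is called triploid when the
#' fitted quadratic opens upward (\eqn{a > 0}) and its symmetry axis
#' \eqn{-b/2a}, rounded to \code{axisDigits} decimals, lies within
#' \code{[axisLo - axisSlack, axisHi + axisSlack]}; an axis inside the slack
#' margin but outside \code{[axisLo, axisHi]} keeps the triploid verdict with
#' an \code{axis_out_of_range} flag, while an axis beyond the slack demotes
#' the verdict to \code{triploid_low_confidence}. Set \code{axisSlack = 0}
#' for the strict rule.
#'
#' @param axisLo,axisHi inclusive axis bounds, defaults 0.45 and 0.55.
#' @param axisSlack extra margin beyond the bounds within which an upward
#'   parabola is still called triploid (flagged), default 0.01.
#' @param axisDigits decimals the axis is rounded to before comparison,
#'   default 2.
#' @param minSites minimum candidate heterozygous sites for a conclusive
#'   verdict, default 1000.
#' @param zFlagThreshold absolute Z score above which the auxiliary
#'   \code{z_outlier} flag is added (never overrides the parabola verdict),
#'   default 3.
#' @param intermediateBand half-width of the band around the ratio value 2
#'   in which an \code{intermediate_counts} flag (possible mosaicism or
#'   contamination) is raised, default 0.1.
#' @return a list of class \code{ClassifyConfig}.
#' @export
classifyConfig <- function(axisLo = 0.45, axisHi = 0.55, axisSlack = 0.01,
                           axisDigits = 2L, minSites = 1000L,
                           zFlagThreshold = 3, intermediateBand = 0.1) {
    stopifnot(axisLo < axisHi, axisSlack >= 0, minSites >= 0,
              zFlagThreshold > 0, intermediateBand >= 0)
    structure(list(axisLo = axisLo, axisHi = axisHi, axisSlack = axisSlack,
                   axisDigits = as.integer(axisDigits),
                   minSites = as.integer(minSites),
                   zFlagThreshold = zFlagThreshold,
                   intermediateBand = intermediateBand),
              class = "ClassifyConfig")
}

#' UPD-scan configuration
#'
#' Per-bin heterozygous-SNP frequency (HSF) classification and run-calling
#' thresholds. A bin is \code{pink} when HSF \eqn{\le} \code{pinkMaxHSF}
#' (loss of heterozygosity consistent with isodisomy), \code{green}
#' otherwise, \code{yellow} when fewer than \code{minInformative} informative
#' sites fall in it, and \code{gap} when at least \code{gapCoverageFrac} of
#' the bin overlaps a declared assembly gap. The scan counts a site as
#' heterozygous only when each allele has at least \code{hetMinReads}
#' supporting reads: a single supporting read is indistinguishable from a
#' sequencing error at typical depths, and error-driven singletons would
#' otherwise lift isodisomic bins above the HSF threshold.
#'
#' @param binSize bin width in bp, default 1 Mb.
#' @param pinkMaxHSF maximum HSF of a low-heterozygosity (pink) bin,
#'   default 0.05; the boundary HSF of exactly 0 is included.
#' @param minInformative minimum informative sites for a reportable HSF,
#'   default 20.
#' @param gapCoverageFrac gap-overlap fraction above which a bin is classed
#'   \code{gap}, default 0.5.
#' @param hetMinReads minimum reads per allele for the scan's heterozygote
#'   definition, default 2.
#' @param wholeChromFrac fraction of a chromosome's informative bins that
#'   must be pink for a whole-chromosome call, default 0.90.
#' @param minRun minimum consecutive pink bins of a segmental call, default 5.
#' @param maxInterruptions yellow/gap bins tolerated inside a run, default 1.
#' @return a list of class \code{UPDConfig}.
#' @export
updConfig <- function(binSize = 1e6, pinkMaxHSF = 0.05, minInformative = 20L,
                      gapCoverageFrac = 0.5, hetMinReads = 2L,
                      wholeChromFrac = 0.90, minRun = 5L,
                      maxInterruptions = 1L) {
    stopifnot(binSize >= 1, pinkMaxHSF > 0, pinkMaxHSF < 1,
              minInformative >= 1, gapCoverageFrac > 0, gapCoverageFrac <= 1,
              hetMinReads >= 1, wholeChromFrac > 0, wholeChromFrac <= 1,
              minRun >= 1, maxInterruptions >= 0)
    structure(list(binSize = as.integer(binSize), pinkMaxHSF = pinkMaxHSF,
                   minInformative = as.integer(minInformative),
                   gapCoverageFrac = gapCoverageFrac,
                   hetMinReads = as.integer(hetMinReads),
                   wholeChromFrac = wholeChromFrac,
                   minRun = as.integer(minRun),
                   maxInterruptions = as.integer(maxInterruptions)),
              class = "UPDConfig")
}

#' QC-guard configuration
#'
#' @param xTolerance relative deviation of the X:autosome depth ratio from
#'   its sex-specific expectation beyond which contamination is flagged,
#'   default 0.25.
#' @param xHetRateRatio X:autosome heterozygosity-rate ratio below which the
#'   apparent sex is called XY, default 0.25.
#' @param xChrom name of the X chromosome, default \code{"chrX"}.
#' @return a list of class \code{QCConfig}.
#' @export
qcConfig <- function(xTolerance = 0.25, xHetRateRatio = 0.25,
                     xChrom = "chrX") {
    stopifnot(xTolerance > 0, xHetRateRatio > 0, xHetRateRatio < 1)
    structure(list(xTolerance = xTolerance, xHetRateRatio = xHetRateRatio,
                   xChrom = xChrom),
              class = "QCConfig")
}

#' Read a run configuration file
#'
#' A plain \code{key: value} text file (YAML subset) whose keys override the
#' defaults of [filterConfig()], [intervalConfig()], [classifyConfig()],
#' [updConfig()] and [qcConfig()], grouped under top-level keys
#' \code{filter}, \code{intervals}, \code{classify}, \code{upd}, \code{qc}.
#' Absent keys keep their defaults; the fully resolved configuration is
#' returned so callers can log it.
#'
#' @param path config file, or \code{NULL} for all defaults.
#' @return named list with elements \code{filter}, \code{intervals},
#'   \code{classify}, \code{upd}, \code{qc}.
#' @export
readRunConfig <- function(path = NULL) {
    raw <- if (is.null(path)) list() else yaml::read_yaml(path)
    build <- function(fun, section) {
        args <- raw[[section]]
        if (is.null(args)) args <- list()
        unknown <- setdiff(names(args), names(formals(fun)))
        if (length(unknown))
            stop("unknown ", section, " config key(s): ",
                 paste(unknown, collapse = ", "))
        do.call(fun, args)
    }
    list(filter = build(filterConfig, "filter"),
         intervals = build(intervalConfig, "intervals"),
         classify = build(classifyConfig, "classify"),
         upd = build(updConfig, "upd"),
         qc = build(qcConfig, "qc"))
}
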