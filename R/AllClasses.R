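#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo keepSeqlevels
NULL

.VALID_BASES <- c("A", "C", "G", "T")

#' SNPSites: biallelic variant sites with per-allele read depths
#'
#' A \linkS4class{GRanges}-derived container in which every range is a single
#' base and the metadata columns carry, per site, the reference and alternate
#' alleles (single bases), the reference- and alternate-supporting read
#' counts, and the population alternate-allele frequency from a common-SNP
#' panel (\code{NA} when the site is not in the panel).
#'
#' @slot .Data inherited \code{GRanges} representation; required metadata
#'   columns are \code{ref}, \code{alt} (character, one of A/C/G/T),
#'   \code{refDepth}, \code{altDepth} (non-negative integers) and
#'   \code{panelAF} (numeric in \eqn{[0,1]} or \code{NA}).
#'
#' @seealso [SNPSites()] for the constructor, [mutationRatio()] for the
#'   per-site alternate-read fraction.
#' @exportClass SNPSites
setClass("SNPSites", contains = "GRanges")

setValidity("SNPSites", function(object) {
    msg <- NULL
    mc <- mcols(object)
    need <- c("ref", "alt", "refDepth", "altDepth", "panelAF")
    missing <- setdiff(need, colnames(mc))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (!all(width(object) == 1L))
            msg <- c(msg, "all sites must have width 1")
        if (!all(mc$ref %in% .VALID_BASES) || !all(mc$alt %in% .VALID_BASES))
            msg <- c(msg, "ref/alt alleles must be single bases A, C, G or T")
        if (any(mc$ref == mc$alt))
            msg <- c(msg, "ref and alt alleles must differ")
        if (any(mc$refDepth < 0L) || any(mc$altDepth < 0L))
            msg <- c(msg, "read depths must be non-negative")
        af <- mc$panelAF[!is.na(mc$panelAF)]
        if (length(af) && (any(af < 0) || any(af > 1)))
            msg <- c(msg, "panelAF must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' SNPPanel: a common-SNP panel with genome geometry
#'
#' Holds the panel of common biallelic SNPs (position, ref/alt alleles,
#' population alternate-allele frequency) that stands in for a dbSNP/1000
#' Genomes frequency resource, together with the chromosome lengths and the
#' assembly gap intervals needed for binned scanning.
#'
#' @slot sites \code{GRanges} with metadata columns \code{ref}, \code{alt},
#'   \code{af}; positions unique per chromosome; seqlengths set.
#' @slot genome single character label for the genome build.
#' @slot gaps \code{GRanges} of assembly gaps (may be empty).
#'
#' @seealso [SNPPanel()], [readPanel()], [simulatePanel()]
#' @exportClass SNPPanel
setClass("SNPPanel",
    representation(sites = "GRanges", genome = "character", gaps = "GRanges"))

setValidity("SNPPanel", function(object) {
    msg <- NULL
    s <- object@sites
    mc <- mcols(s)
    if (!all(c("ref", "alt", "af") %in% colnames(mc)))
        return("panel sites need metadata columns ref, alt, af")
    if (length(s)) {
        if (anyDuplicated(paste0(seqnames(s), ":", start(s))))
            msg <- c(msg, "panel positions must be unique per chromosome")
        if (any(mc$af < 0) || any(mc$af > 1))
            msg <- c(msg, "panel allele frequencies must lie in [0, 1]")
    }
    sl <- seqlengths(s)
    if (any(is.na(sl)))
        msg <- c(msg, "all panel chromosomes need a declared length")
    else if (length(sl) && any(sl <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (length(object@genome) != 1L)
        msg <- c(msg, "genome must be a single label")
    if (is.null(msg)) TRUE else msg
})

#' IntervalCounts: site counts in the three mutation-ratio intervals
#'
#' Counts of candidate heterozygous sites whose mutation ratio (alternate-read
#' fraction) falls in the 1/3, 1/2 and 2/3 intervals, plus the total number of
#' candidate sites (sites outside all three intervals count only there).
#'
#' @slot nThird,nHalf,nTwoThirds non-negative integer counts.
#' @slot nCandidates total candidate heterozygous sites considered.
#' @exportClass IntervalCounts
setClass("IntervalCounts",
    representation(nThird = "integer", nHalf = "integer",
                   nTwoThirds = "integer", nCandidates = "integer"))

setValidity("IntervalCounts", function(object) {
    n <- c(object@nThird, object@nHalf, object@nTwoThirds, object@nCandidates)
    if (any(n < 0L)) return("counts must be non-negative")
    if (sum(n[1:3]) > n[4])
        return("interval counts cannot exceed the candidate total")
    TRUE
})

#' ParabolaFit: exact quadratic through the three interval ordinates
#'
#' The quadratic \eqn{y = ax^2 + bx + c} interpolating the three points
#' \eqn{(1/3, y_1)}, \eqn{(1/2, y_2)}, \eqn{(2/3, y_3)}, where the ordinates
#' are the interval counts normalised to sum to one. The symmetry axis is
#' \eqn{-b/(2a)} (NA when \eqn{a = 0}).
#'
#' @slot a,b,c quadratic coefficients.
#' @slot axis abscissa of the vertex, \eqn{-b/(2a)}; \code{NA} when undefined.
#' @slot y numeric(3) normalised ordinates \eqn{(y_1, y_2, y_3)}.
#' @slot degenerate \code{TRUE} when all three interval counts were zero.
#' @exportClass ParabolaFit
setClass("ParabolaFit",
    representation(a = "numeric", b = "numeric", c = "numeric",
                   axis = "numeric", y = "numeric", degenerate = "logical"))

setValidity("ParabolaFit", function(object) {
    if (object@degenerate) return(TRUE)
    if (length(object@y) != 3L) return("y must have length 3")
    if (abs(sum(object@y) - 1) > 1e-9) return("ordinates must sum to 1")
    TRUE
})

#' BatchStats: reference mean and SD for the within-batch Z test
#'
#' @slot mean,sd reference mean and standard deviation of the ratio statistic.
#' @slot nReference number of samples the statistics were computed from.
#' @slot robust whether presumed-triploid samples (ratio > 2) were excluded.
#' @exportClass BatchStats
setClass("BatchStats",
    representation(mean = "numeric", sd = "numeric", nReference = "integer",
                   robust = "logical"))

setValidity("BatchStats", function(object) {
    if (!is.na(object@sd) && object@sd < 0) return("sd must be non-negative")
    if (object@nReference < 2L) return("need at least 2 reference samples")
    TRUE
})

#' PloidyCall: per-sample ploidy verdict with supporting statistics
#'
#' Bundles, for one sample, the ratio statistic
#' \eqn{(n_{1/3} + n_{2/3}) / n_{1/2}}, the exact quadratic fit, the optional
#' within-batch Z score, QC flags, and the verdict: one of \code{"diploid"},
#' \code{"triploid"}, \code{"triploid_low_confidence"} or
#' \code{"inconclusive"}.
#'
#' @slot sampleId sample identifier.
#' @slot ratio ratio statistic; \code{NA} when the 1/2-interval count is zero.
#' @slot fit a \linkS4class{ParabolaFit}.
#' @slot z within-batch Z score, \code{NA} when no batch was available.
#' @slot verdict character verdict (see above).
#' @slot flags character vector of QC flags (possibly empty): subsets of
#'   \code{low_sites}, \code{axis_out_of_range}, \code{degenerate_fit},
#'   \code{undefined_ratio}, \code{intermediate_counts},
#'   \code{z_outlier}, \code{possible_contamination}.
#' @slot counts the \linkS4class{IntervalCounts} the call is based on.
#' @exportClass PloidyCall
setClass("PloidyCall",
    representation(sampleId = "character", ratio = "numeric",
                   fit = "ParabolaFit", z = "numeric", verdict = "character",
                   flags = "character", counts = "IntervalCounts"))

.VERDICTS <- c("diploid", "triploid", "triploid_low_confidence",
               "inconclusive")

setValidity("PloidyCall", function(object) {
    if (!object@verdict %in% .VERDICTS)
        return(paste("verdict must be one of:", paste(.VERDICTS,
                     collapse = ", ")))
    if (object@verdict == "inconclusive" && length(object@flags) == 0L)
        return("an inconclusive verdict requires at least one flag")
    TRUE
})
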