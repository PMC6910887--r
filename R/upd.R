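#' Per-bin heterozygous-SNP frequencies
#'
#' Partitions every panel chromosome into consecutive bins (default 1 Mb;
#' the last bin of a chromosome is truncated) and computes, per bin, the
#' heterozygous-SNP frequency (HSF): the fraction of informative sites —
#' covered panel sites passing the depth filter — that look heterozygous
#' (each allele supported by at least \code{updCfg$hetMinReads} reads).
#' Covered sites, not all panel sites, form the denominator so that
#' low-coverage bins do not masquerade as loss of heterozygosity.
#'
#' Each bin is coloured: \code{gap} when it overlaps declared assembly gaps
#' over at least \code{gapCoverageFrac} of its width; otherwise
#' \code{yellow} (poor data quality, HSF unreported) when it has fewer than
#' \code{minInformative} informative sites; otherwise \code{pink} when HSF
#' \eqn{\le} \code{pinkMaxHSF} (LOH consistent with isodisomic UPD) or
#' \code{green} when above.
#'
#' @param sites a \linkS4class{SNPSites} object (unfiltered; the same
#'   panel/depth filter as the ploidy analysis is applied internally).
#' @param panel a \linkS4class{SNPPanel} with chromosome lengths (and
#'   optionally gaps).
#' @param filterCfg a [filterConfig()] for panel/depth filtering.
#' @param updCfg an [updConfig()].
#' @return a \code{GRanges}, one range per bin in genomic order, with
#'   metadata columns \code{nHet}, \code{nInformative}, \code{hsf}
#'   (\code{NA} for yellow/gap bins) and \code{color}.
#' @seealso [callUPD()]
#' @export
binHSF <- function(sites, panel, filterCfg = filterConfig(),
                   updCfg = updConfig()) {
    sl <- seqlengths(panelSites(panel))
    unknown <- setdiff(unique(as.character(seqnames(sites))), names(sl))
    if (length(unknown))
        stop("site chromosome(s) not in panel: ",
             paste(unknown, collapse = ", "))

    kept <- filterSites(sites, panel, filterCfg)
    k <- updCfg$hetMinReads
    isHet <- refDepth(kept) >= k & altDepth(kept) >= k

    bins <- GenomicRanges::tileGenome(sl, tilewidth = updCfg$binSize,
                                      cut.last.tile.in.chrom = TRUE)
    ovInf <- GenomicRanges::countOverlaps(bins, kept)
    ovHet <- GenomicRanges::countOverlaps(bins, kept[isHet])

    gapFrac <- rep(0, length(bins))
    gaps <- panelGaps(panel)
    if (length(gaps)) {
        seqlevels(gaps) <- seqlevels(bins)
        cov <- GenomicRanges::intersect(bins, gaps, ignore.strand = TRUE)
        hits <- GenomicRanges::findOverlaps(bins, cov)
        w <- tapply(width(cov)[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_along(bins)), sum)
        w[is.na(w)] <- 0
        gapFrac <- as.numeric(w) / width(bins)
    }

    color <- ifelse(gapFrac >= updCfg$gapCoverageFrac, "gap",
             ifelse(ovInf < updCfg$minInformative, "yellow",
             ifelse(ovHet / ovInf <= updCfg$pinkMaxHSF, "pink", "green")))
    hsf <- ifelse(color %in% c("pink", "green"), ovHet / pmax(ovInf, 1L),
                  NA_real_)
    mcols(bins) <- DataFrame(nHet = ovHet, nInformative = ovInf,
                             hsf = hsf, color = color)
    bins
}

#' Call whole-chromosome and segmental UPD/LOH regions
#'
#' From the per-bin HSF track: a chromosome on which at least
#' \code{wholeChromFrac} of the informative (non-yellow, non-gap) bins are
#' pink yields one \code{whole_chromosome} call spanning the full
#' chromosome. Otherwise maximal runs of at least \code{minRun} pink bins —
#' tolerating up to \code{maxInterruptions} intervening yellow/gap bins per
#' run, with green bins always terminating a run — are emitted as
#' \code{segmental} calls spanning the first to the last pink bin of the
#' run. The calls describe LOH consistent with isodisomic UPD; parental
#' origin cannot be established without trio genotypes.
#'
#' @param bins output of [binHSF()].
#' @param updCfg an [updConfig()].
#' @return a \code{GRanges} (possibly empty) with metadata columns
#'   \code{kind} (\code{whole_chromosome}/\code{segmental}),
#'   \code{nPinkBins} and \code{fractionPink} (pink fraction of the
#'   chromosome's informative bins).
#' @export
callUPD <- function(bins, updCfg = updConfig()) {
    out <- GRanges(seqinfo = seqinfo(bins))
    mcols(out) <- DataFrame(kind = character(), nPinkBins = integer(),
                            fractionPink = numeric())
    for (chr in seqlevels(bins)) {
        b <- bins[seqnames(bins) == chr]
        if (!length(b)) next
        color <- mcols(b)$color
        informative <- color %in% c("pink", "green")
        nInfo <- sum(informative)
        nPink <- sum(color == "pink")
        fracPink <- if (nInfo > 0) nPink / nInfo else NA_real_
        if (nInfo >= updCfg$minRun && !is.na(fracPink) &&
            fracPink >= updCfg$wholeChromFrac) {
            call <- GRanges(chr, IRanges(1L, seqlengths(bins)[[chr]]),
                            seqinfo = seqinfo(bins))
            mcols(call) <- DataFrame(kind = "whole_chromosome",
                                     nPinkBins = as.integer(nPink),
                                     fractionPink = fracPink)
            out <- c(out, call)
            next
        }
        runs <- .pinkRuns(color, updCfg)
        for (r in runs) {
            call <- GRanges(chr, IRanges(start(b)[r[1]], end(b)[r[2]]),
                            seqinfo = seqinfo(bins))
            nP <- sum(color[r[1]:r[2]] == "pink")
            mcols(call) <- DataFrame(kind = "segmental",
                                     nPinkBins = as.integer(nP),
                                     fractionPink = fracPink)
            out <- c(out, call)
        }
    }
    out
}

# Maximal runs of pink bins: green ends a run; yellow/gap bins are tolerated
# inside a run up to maxInterruptions (runs still start and end on pink).
# Returns a list of c(firstBinIndex, lastBinIndex).
.pinkRuns <- function(color, updCfg) {
    runs <- list()
    n <- length(color)
    i <- 1L
    while (i <= n) {
        if (color[i] != "pink") { i <- i + 1L; next }
        first <- i
        last <- i
        nPink <- 1L
        interruptions <- 0L
        j <- i + 1L
        while (j <= n) {
            if (color[j] == "pink") {
                last <- j
                nPink <- nPink + 1L
            } else if (color[j] %in% c("yellow", "gap")) {
                interruptions <- interruptions + 1L
                if (interruptions > updCfg$maxInterruptions) break
            } else break
            j <- j + 1L
        }
        if (nPink >= updCfg$minRun)
            runs <- c(runs, list(c(first, last)))
        i <- max(j, last + 1L)
    }
    runs
}
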