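#' Construct a common-SNP panel
#'
#' The panel enumerates the common biallelic SNPs (with population
#' alternate-allele frequencies) against which sample sites are matched, and
#' carries the genome geometry (chromosome lengths, assembly gaps) used by
#' the binned heterozygosity scan.
#'
#' @param chrom,pos,ref,alt,af vectors describing the panel sites; \code{af}
#'   is the population alternate-allele frequency in \eqn{[0,1]}.
#' @param seqlengths named integer vector of chromosome lengths (required for
#'   every chromosome used).
#' @param genome single character genome-build label.
#' @param gaps optional \code{GRanges} of assembly gaps.
#' @return a \linkS4class{SNPPanel}.
#' @examples
#' SNPPanel("chr1", c(100, 200), "A", c("G", "T"), c(0.2, 0.4),
#'          seqlengths = c(chr1 = 1e6))
#' @export
SNPPanel <- function(chrom = character(), pos = integer(),
                     ref = character(), alt = character(), af = numeric(),
                     seqlengths, genome = "synthetic",
                     gaps = GRanges()) {
    si <- Seqinfo(names(seqlengths), seqlengths = as.integer(seqlengths),
                  genome = genome)
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  ref = as.character(ref), alt = as.character(alt),
                  af = as.numeric(af), seqinfo = si)
    gr <- sort(gr)
    if (length(gaps)) {
        seqlevels(gaps) <- seqlevels(si)
        seqinfo(gaps) <- si
    } else {
        gaps <- GRanges(seqinfo = si)
    }
    new("SNPPanel", sites = gr, genome = genome, gaps = gaps)
}

#' @describeIn SNPPanel the panel sites as a \code{GRanges} (metadata columns
#'   \code{ref}, \code{alt}, \code{af}).
#' @param x a \linkS4class{SNPPanel}.
#' @export
setMethod("panelSites", "SNPPanel", function(x) x@sites)

#' @describeIn SNPPanel the declared assembly gaps as a \code{GRanges}.
#' @export
setMethod("panelGaps", "SNPPanel", function(x) x@gaps)

setMethod("show", "SNPPanel", function(object) {
    sl <- seqlengths(object@sites)
    cat("SNPPanel (", object@genome, "): ", length(object@sites),
        " site(s) on ", length(sl), " chromosome(s); ",
        length(object@gaps), " gap interval(s)\n", sep = "")
})

#' @describeIn SNPPanel number of panel sites.
#' @export
setMethod("length", "SNPPanel", function(x) length(x@sites))
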