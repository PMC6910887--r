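#' Construct a set of biallelic SNP sites
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt single-base reference/alternate alleles (A/C/G/T).
#' @param refDepth,altDepth non-negative read counts supporting each allele.
#' @param panelAF population alternate-allele frequency in \eqn{[0,1]};
#'   \code{NA} for sites absent from the panel.
#' @param seqinfo optional \code{Seqinfo} giving chromosome lengths.
#'
#' @return a \linkS4class{SNPSites} object.
#' @examples
#' SNPSites("chr1", 100, "A", "G", 7, 8)
#' @export
SNPSites <- function(chrom = character(), pos = integer(),
                     ref = character(), alt = character(),
                     refDepth = integer(), altDepth = integer(),
                     panelAF = NA_real_, seqinfo = NULL) {
    n <- length(pos)
    panelAF <- rep_len(as.numeric(panelAF), n)
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  ref = as.character(ref), alt = as.character(alt),
                  refDepth = as.integer(refDepth),
                  altDepth = as.integer(altDepth),
                  panelAF = panelAF)
    if (!is.null(seqinfo))
        seqinfo(gr) <- merge(seqinfo(gr), seqinfo)
    new("SNPSites", gr)
}

#' Accessors for SNPSites
#'
#' Per-site alleles, allele-specific read depths, total depth, and panel
#' allele frequency.
#'
#' @param x a \linkS4class{SNPSites} object.
#' @return a vector with one element per site.
#' @name SNPSites-accessors
#' @aliases refAllele altAllele refDepth altDepth totalDepth panelAF
NULL

#' @rdname SNPSites-accessors
#' @export
setMethod("refAllele", "SNPSites", function(x) mcols(x)$ref)

#' @rdname SNPSites-accessors
#' @export
setMethod("altAllele", "SNPSites", function(x) mcols(x)$alt)

#' @rdname SNPSites-accessors
#' @export
setMethod("refDepth", "SNPSites", function(x) mcols(x)$refDepth)

#' @rdname SNPSites-accessors
#' @export
setMethod("altDepth", "SNPSites", function(x) mcols(x)$altDepth)

#' @rdname SNPSites-accessors
#' @export
setMethod("totalDepth", "SNPSites",
    function(x) mcols(x)$refDepth + mcols(x)$altDepth)

#' @rdname SNPSites-accessors
#' @export
setMethod("panelAF", "SNPSites", function(x) mcols(x)$panelAF)

#' Per-site mutation ratio
#'
#' The mutation ratio (MR) of a site is the fraction of reads supporting the
#' alternate allele, \code{altDepth / (refDepth + altDepth)} — the low-depth
#' analogue of the B-allele fraction. Heterozygous sites concentrate near 1/2
#' in diploids and near 1/3 or 2/3 in triploids.
#'
#' @param x a \linkS4class{SNPSites} object.
#' @param ... unused.
#' @return numeric vector of MR values in \eqn{[0,1]}.
#' @examples
#' mutationRatio(SNPSites("chr1", 1:2, "A", "G", c(5, 20), c(5, 10)))
#' @export
setMethod("mutationRatio", "SNPSites", function(x, ...) {
    tot <- totalDepth(x)
    if (any(tot == 0L))
        stop("mutation ratio undefined at zero total depth; ",
             "filter sites first (", sum(tot == 0L), " offending site(s))")
    altDepth(x) / tot
})

setMethod("show", "SNPSites", function(object) {
    cat("SNPSites with", length(object), "site(s)\n")
    if (length(object)) {
        callNextMethod()
    }
})
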