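#' Select candidate SNPs for ploidy analysis
#'
#' Applies the candidate-site rules: the site must (i) match the common-SNP
#' panel on chromosome, position and both alleles, (ii) have a population
#' alternate-allele frequency above \code{cfg$minPanelAF}, and (iii) carry at
#' least \code{cfg$minTotalDepth} reads in total. When a retained site lacks
#' a stored panel AF, the panel's value is filled in. Removal is attributed
#' to the first failing criterion in the order panel, frequency, depth, and
#' the per-criterion counts are stored in
#' \code{metadata(result)$removed} (so removed + retained = input).
#'
#' Filtering preserves input order, never duplicates sites, and is
#' idempotent.
#'
#' @param sites a \linkS4class{SNPSites} object.
#' @param panel a \linkS4class{SNPPanel}.
#' @param cfg a [filterConfig()].
#' @return the retained \linkS4class{SNPSites}, with removal counts in
#'   \code{metadata()}.
#' @export
filterSites <- function(sites, panel, cfg = filterConfig()) {
    if (cfg$requirePanel && length(panel) == 0L)
        stop("empty SNP panel with requirePanel = TRUE")
    if (length(sites) == 0L) {
        metadata(sites)$removed <- c(not_in_panel = 0L, low_panel_af = 0L,
                                     low_depth = 0L)
        return(sites)
    }
    ps <- panelSites(panel)
    key <- function(chr, pos, ref, alt) paste(chr, pos, ref, alt, sep = ":")
    pkey <- key(seqnames(ps), start(ps), mcols(ps)$ref, mcols(ps)$alt)
    skey <- key(seqnames(sites), start(sites), refAllele(sites),
                altAllele(sites))
    hit <- match(skey, pkey)

    inPanel <- !is.na(hit)
    af <- panelAF(sites)
    af[inPanel] <- mcols(ps)$af[hit[inPanel]]
    mcols(sites)$panelAF <- af

    okPanel <- if (cfg$requirePanel) inPanel else rep(TRUE, length(sites))
    okAF <- !is.na(af) & af > cfg$minPanelAF
    okDepth <- totalDepth(sites) >= cfg$minTotalDepth

    removed <- c(not_in_panel = sum(!okPanel),
                 low_panel_af = sum(okPanel & !okAF),
                 low_depth = sum(okPanel & okAF & !okDepth))
    out <- sites[okPanel & okAF & okDepth]
    metadata(out)$removed <- removed
    out
}

#' Select observationally heterozygous sites
#'
#' A site is treated as heterozygous when both alleles are supported by at
#' least \code{cfg$hetMinMinorReads} reads. The diploid-model genotype field
#' of a VCF is deliberately ignored: genotype calls made under a diploid
#' prior are unreliable in triploid samples. Sites whose MR falls outside
#' every counting interval are harmless downstream — the intervals are the
#' real gate.
#'
#' @inheritParams filterSites
#' @return the heterozygous subset of \code{sites}, in input order.
#' @export
selectHeterozygous <- function(sites, cfg = filterConfig()) {
    k <- cfg$hetMinMinorReads
    sites[refDepth(sites) >= k & altDepth(sites) >= k]
}
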