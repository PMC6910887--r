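#' Read biallelic SNP sites from a VCF
#'
#' Extracts one \linkS4class{SNPSites} entry per biallelic SNV record for the
#' named sample, taking the reference/alternate read counts from the
#' per-sample allelic-depth (\code{AD}) field. Multi-allelic records,
#' non-SNV records (including INDELs) and records without allelic depths are
#' skipped; the skip counts are kept in
#' \code{metadata(result)$skipped} and reported via \code{message()}.
#' Records with zero depths are retained — depth filtering is a later,
#' explicit step.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param sampleId sample column to read; must exist in the VCF header.
#' @return a \linkS4class{SNPSites} object (panel AF unset).
#' @seealso [readSiteTable()] for the plain-text equivalent.
#' @export
readVcfSites <- function(path, sampleId) {
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    hdr.samples <- colnames(vcf)
    if (!sampleId %in% hdr.samples)
        stop("sample '", sampleId, "' not in VCF header (found: ",
             paste(hdr.samples, collapse = ", "), ")")
    if (!"AD" %in% rownames(VariantAnnotation::geno(
            VariantAnnotation::header(vcf))))
        stop("VCF lacks a per-sample allelic-depth (AD) FORMAT field")

    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(VariantAnnotation::ref(vcf))
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altList)

    multi <- nAlt != 1L
    alts <- rep(NA_character_, length(vcf))
    alts[!multi] <- as.character(unlist(altList[!multi]))
    snv <- !multi & refs %in% .VALID_BASES & alts %in% .VALID_BASES

    ad <- VariantAnnotation::geno(vcf)$AD[, sampleId]
    adLen <- lengths(ad)
    adOK <- adLen == 2L &
        !vapply(ad, function(v) any(is.na(v)), logical(1))
    keep <- snv & adOK

    skipped <- c(multiallelic = sum(multi),
                 not_snv = sum(!snv & !multi),
                 no_allelic_depth = sum(snv & !adOK))
    if (any(skipped > 0))
        message("readVcfSites: skipped ", sum(skipped), " record(s) (",
                paste(names(skipped), skipped, sep = "=", collapse = ", "),
                ")")

    adm <- matrix(unlist(ad[keep]), ncol = 2L, byrow = TRUE)
    out <- SNPSites(chrom = as.character(seqnames(rr))[keep],
                    pos = start(rr)[keep],
                    ref = refs[keep], alt = alts[keep],
                    refDepth = adm[, 1L], altDepth = adm[, 2L])
    metadata(out)$skipped <- skipped
    out
}

.SITE_COLS <- c("chrom", "pos", "ref", "alt", "ref_depth", "alt_depth",
                "panel_af")

#' Read and write plain-text site tables
#'
#' The site table is a tab-separated file with the exact header
#' \code{chrom pos ref alt ref_depth alt_depth panel_af} (1-based positions;
#' \code{panel_af} may be empty for sites absent from the panel). Parsing is
#' order-preserving; malformed depths are reported with their line number.
#'
#' @param path file path.
#' @return [readSiteTable()]: a \linkS4class{SNPSites} object in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeSiteTable(SNPSites("chr2", 100, "C", "T", 12, 11, 0.31), f)
#' readSiteTable(f)
#' @export
readSiteTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, .SITE_COLS))
        stop("site table header must be exactly: ",
             paste(.SITE_COLS, collapse = "\t"))
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "character",
                                           "character", "character",
                                           "numeric"),
                            na.strings = "", quote = "",
                            comment.char = "")
    if (nrow(df) == 0L) return(SNPSites())
    for (col in c("ref_depth", "alt_depth")) {
        v <- suppressWarnings(as.integer(df[[col]]))
        bad <- which(is.na(v) | v < 0L)
        if (length(bad))
            stop("invalid ", col, " '", df[[col]][bad[1]], "' at line ",
                 bad[1] + 1L, " of ", path)
        df[[col]] <- v
    }
    SNPSites(df$chrom, df$pos, df$ref, df$alt,
             df$ref_depth, df$alt_depth, df$panel_af)
}

#' @rdname readSiteTable
#' @param sites a \linkS4class{SNPSites} object to serialise.
#' @export
writeSiteTable <- function(sites, path) {
    df <- data.frame(chrom = as.character(seqnames(sites)),
                     pos = start(sites),
                     ref = refAllele(sites), alt = altAllele(sites),
                     ref_depth = refDepth(sites),
                     alt_depth = altDepth(sites),
                     panel_af = panelAF(sites))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Read a common-SNP panel from plain-text files
#'
#' @param path tab-separated panel with header
#'   \code{chrom pos ref alt af}.
#' @param sizesPath two-column tab-separated file (no header) of chromosome
#'   name and length.
#' @param gapsPath optional BED file (0-based half-open) of assembly gaps.
#' @param genome genome-build label.
#' @return a \linkS4class{SNPPanel}.
#' @export
readPanel <- function(path, sizesPath, gapsPath = NULL,
                      genome = "unknown") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "character",
                                           "numeric"),
                            quote = "", comment.char = "")
    if (!identical(colnames(df), c("chrom", "pos", "ref", "alt", "af")))
        stop("panel header must be: chrom\tpos\tref\talt\taf")
    sizes <- readChromSizes(sizesPath)
    gaps <- if (is.null(gapsPath)) GRanges() else
        rtracklayer::import(gapsPath, format = "BED")
    SNPPanel(df$chrom, df$pos, df$ref, df$alt, df$af,
             seqlengths = sizes, genome = genome, gaps = granges(gaps))
}

#' @rdname readPanel
#' @param panel a \linkS4class{SNPPanel} to serialise (sites only; sizes and
#'   gaps are written to the companion paths when given).
#' @export
writePanel <- function(panel, path, sizesPath = NULL, gapsPath = NULL) {
    s <- panelSites(panel)
    df <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                     ref = mcols(s)$ref, alt = mcols(s)$alt,
                     af = mcols(s)$af)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sizesPath)) {
        sl <- seqlengths(s)
        utils::write.table(data.frame(names(sl), unname(sl)), sizesPath,
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    if (!is.null(gapsPath))
        rtracklayer::export(panelGaps(panel), gapsPath, format = "BED")
    invisible(path)
}

#' Read a chromosome-sizes file
#'
#' @param path two-column tab-separated file: chromosome name, length.
#' @return named integer vector of lengths.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            colClasses = c("character", "integer"))
    stats::setNames(df[[2]], df[[1]])
}

.kv <- function(key, value) {
    if (is.numeric(value))
        value <- format(value, digits = 15, trim = TRUE, scientific = FALSE)
    paste0(key, ": ", paste(value, collapse = ","))
}

#' Write the per-sample report and UPD track
#'
#' Serialises a \linkS4class{PloidyCall} (and optionally the UPD scan) as
#' deterministic, machine-readable \code{key: value} text including all
#' statistics, the thresholds used, QC flags, and the package version.
#' UPD calls are additionally written as a BED track (0-based half-open).
#'
#' @param call a \linkS4class{PloidyCall}.
#' @param path output file for the report.
#' @param upd optional \code{GRanges} of UPD calls from [callUPD()].
#' @param updPath output BED path for the UPD track (required when
#'   \code{upd} is given).
#' @param config optional resolved configuration (from [readRunConfig()] or
#'   the individual constructors) to log.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(call, path, upd = NULL, updPath = NULL,
                        config = NULL) {
    cnt <- call@counts
    lines <- c(
        .kv("software", "SNPloidy"),
        .kv("version", as.character(utils::packageVersion("SNPloidy"))),
        .kv("sample_id", call@sampleId),
        .kv("verdict", call@verdict),
        .kv("ratio_statistic", call@ratio),
        .kv("parabola_a", call@fit@a),
        .kv("parabola_b", call@fit@b),
        .kv("parabola_c", call@fit@c),
        .kv("axis", call@fit@axis),
        .kv("z_score", call@z),
        .kv("n_third", cnt@nThird),
        .kv("n_half", cnt@nHalf),
        .kv("n_two_thirds", cnt@nTwoThirds),
        .kv("n_candidate_sites", cnt@nCandidates),
        .kv("flags", if (length(call@flags)) call@flags else "none"))
    if (!is.null(config)) {
        flat <- unlist(config)
        lines <- c(lines,
                   vapply(names(flat), function(k)
                       .kv(paste0("config.", k), flat[[k]]), character(1)))
    }
    writeLines(lines, path)
    if (!is.null(upd)) {
        if (is.null(updPath)) stop("updPath required when upd is given")
        writeUpdBed(upd, updPath)
    }
    invisible(path)
}

#' @rdname writeReport
#' @export
writeUpdBed <- function(upd, updPath) {
    con <- file(updPath, "w")
    on.exit(close(con))
    writeLines(paste0("# SNPloidy UPD calls (LOH consistent with ",
                      "isodisomic UPD; parental origin not established)"),
               con)
    if (length(upd)) {
        df <- data.frame(chrom = as.character(seqnames(upd)),
                         start = start(upd) - 1L, end = end(upd),
                         name = paste0(mcols(upd)$kind, "_",
                                       seq_along(upd)),
                         score = round(
                             1000 * mcols(upd)$fractionPink),
                         strand = ".")
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(updPath)
}
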