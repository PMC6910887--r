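#' Simulation configuration
#'
#' Describes one synthetic low-coverage WGS sample at the level the method
#' consumes: per-site allele depths at common-SNP panel positions. The
#' default synthetic genome has four 100-Mb autosomes plus a 100-Mb X
#' chromosome with 5000 panel sites each; panel alternate-allele frequencies
#' are uniform on \eqn{[0.05, 0.95]} — common SNPs, as the frequency filter
#' requires, with a spectrum symmetric in alternate vs reference so that the
#' two triploid heterozygote classes (AAB and ABB) are balanced and the
#' fitted symmetry axis sits near 0.5, as observed in confirmed triploids;
#' a low-skewed alternate-AF spectrum shifts the axis upward instead.
#' Fetal genotypes are drawn under Hardy–Weinberg for the given
#' ploidy: triploid heterozygotes are AAB (expected alternate fraction 1/3)
#' or ABB (2/3) according to the genotype draw. Depth is Poisson with mean
#' \code{meanDepth} on autosomes, scaled by X copy number for the sex
#' chromosome. Alternate reads are binomial with a success probability that
#' mixes the fetal allele fraction with an independently drawn maternal
#' (46,XX) diploid genotype at weight \code{maternalFraction}, applies the
#' mosaic diploid subpopulation at weight \code{mosaicFraction}, and applies
#' the symmetric per-read error rate \code{errorRate} (so homozygous sites
#' show alternate fractions near \eqn{\epsilon} or \eqn{1-\epsilon}).
#' Sites inside \code{updRegions} are forced to fetal homozygosity
#' (isodisomy).
#'
#' @param ploidy \code{"diploid"} or \code{"triploid"}.
#' @param sex karyotype sex: one of XX, XY (diploid) or XXX, XXY, XYY
#'   (triploid analogues).
#' @param nSitesPerChrom panel sites per chromosome.
#' @param chromLengths named vector of chromosome lengths; include
#'   \code{"chrX"} for a sex chromosome.
#' @param meanDepth Poisson mean read depth per site.
#' @param errorRate symmetric per-read error rate \eqn{\epsilon}.
#' @param maternalFraction maternal-cell contamination fraction in
#'   \eqn{[0, 0.5]}.
#' @param mosaicFraction fraction of cells with the \emph{other} ploidy
#'   (diploid subpopulation in a triploid sample and vice versa).
#' @param updRegions \code{GRanges} (or \code{NULL}) of regions forced to
#'   fetal homozygosity.
#' @param afRange range of the uniform panel-AF distribution.
#' @param seed integer seed; fixed seed gives identical output.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(ploidy = c("diploid", "triploid"),
                      sex = NULL,
                      nSitesPerChrom = 5000L,
                      chromLengths = c(chr1 = 1e8, chr2 = 1e8, chr3 = 1e8,
                                       chr4 = 1e8, chrX = 1e8),
                      meanDepth = 15,
                      errorRate = 0.002,
                      maternalFraction = 0,
                      mosaicFraction = 0,
                      updRegions = NULL,
                      afRange = c(0.05, 0.95),
                      seed = 1L) {
    ploidy <- match.arg(ploidy)
    if (is.null(sex)) sex <- if (ploidy == "diploid") "XX" else "XXX"
    okSex <- if (ploidy == "diploid") c("XX", "XY") else
        c("XXX", "XXY", "XYY")
    if (!sex %in% okSex)
        stop("sex '", sex, "' invalid for ", ploidy, " (allowed: ",
             paste(okSex, collapse = ", "), ")")
    stopifnot(nSitesPerChrom >= 1, meanDepth > 0,
              errorRate >= 0, errorRate < 0.5,
              maternalFraction >= 0, maternalFraction <= 0.5,
              mosaicFraction >= 0, mosaicFraction <= 1,
              length(afRange) == 2L, afRange[1] >= 0, afRange[2] <= 1,
              afRange[1] < afRange[2], all(chromLengths > 0))
    structure(list(ploidy = ploidy, sex = sex,
                   nSitesPerChrom = as.integer(nSitesPerChrom),
                   chromLengths = chromLengths, meanDepth = meanDepth,
                   errorRate = errorRate,
                   maternalFraction = maternalFraction,
                   mosaicFraction = mosaicFraction,
                   updRegions = updRegions, afRange = afRange,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

# X copy number implied by the karyotype sex.
.xCopies <- function(sex) {
    switch(sex, XX = 2L, XY = 1L, XXX = 3L, XXY = 2L, XYY = 1L,
           stop("unknown sex: ", sex))
}

#' Generate a synthetic common-SNP panel
#'
#' Panel positions are drawn uniformly (without replacement, sorted) along
#' each chromosome of \code{cfg$chromLengths}; allele frequencies uniformly
#' from \code{cfg$afRange}; ref/alt drawn from A/C/G/T.
#'
#' @param cfg a [simConfig()].
#' @param gaps optional \code{GRanges} of assembly gaps to declare.
#' @return a \linkS4class{SNPPanel}.
#' @export
simulatePanel <- function(cfg = simConfig(), gaps = GRanges()) {
    set.seed(cfg$seed)
    chroms <- names(cfg$chromLengths)
    pieces <- lapply(chroms, function(chr) {
        pos <- sort(sample.int(cfg$chromLengths[[chr]],
                               cfg$nSitesPerChrom))
        ref <- sample(.VALID_BASES, cfg$nSitesPerChrom, replace = TRUE)
        alt <- vapply(ref, function(r)
            sample(setdiff(.VALID_BASES, r), 1L), character(1))
        data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                   af = stats::runif(cfg$nSitesPerChrom,
                                     cfg$afRange[1], cfg$afRange[2]))
    })
    df <- do.call(rbind, pieces)
    SNPPanel(df$chrom, df$pos, df$ref, df$alt, df$af,
             seqlengths = cfg$chromLengths, genome = "synthetic",
             gaps = gaps)
}

#' Simulate one sample's per-site allele depths
#'
#' Implements the generative model the classifier inverts (see
#' [simConfig()] for the model description). The returned truth record
#' stores every latent state: per-site fetal allele count and copy number,
#' effective fetal fraction, maternal genotype, and the final binomial
#' success probability.
#'
#' @param cfg a [simConfig()].
#' @param panel optional \linkS4class{SNPPanel}; generated from \code{cfg}
#'   (with a seed derived from \code{cfg$seed}) when omitted.
#' @return list with \code{sites} (a \linkS4class{SNPSites}), \code{panel},
#'   and \code{truth} (a list: config echo plus per-site latent states).
#' @examples
#' sim <- simulateSample(simConfig(ploidy = "triploid", seed = 7,
#'                                 nSitesPerChrom = 200))
#' mean(mutationRatio(selectHeterozygous(sim$sites)))
#' @export
simulateSample <- function(cfg = simConfig(), panel = NULL) {
    if (is.null(panel)) {
        pcfg <- cfg
        # panel seed offset keeps site draws independent of panel draws
        pcfg$seed <- cfg$seed + 1000003L
        panel <- simulatePanel(pcfg)
    }
    set.seed(cfg$seed)
    ps <- panelSites(panel)
    n <- length(ps)
    af <- mcols(ps)$af
    chrom <- as.character(seqnames(ps))
    isX <- chrom == "chrX"

    basePloidy <- if (cfg$ploidy == "diploid") 2L else 3L
    cn <- ifelse(isX, .xCopies(cfg$sex), basePloidy)

    # fetal alternate-allele count under Hardy-Weinberg at copy number cn
    g <- stats::rbinom(n, cn, af)

    # isodisomy: forced fetal homozygosity inside declared UPD regions
    if (!is.null(cfg$updRegions) && length(cfg$updRegions)) {
        inUPD <- IRanges::overlapsAny(ps, cfg$updRegions)
        g[inUPD] <- cn[inUPD] * stats::rbinom(sum(inUPD), 1L, af[inUPD])
    }
    f <- g / cn

    # mosaic subpopulation of the other ploidy: derive its genotype from the
    # same zygote by dropping (triploid->diploid) or duplicating a
    # homologue, then mix allele fractions cell-wise
    fEff <- f
    if (cfg$mosaicFraction > 0) {
        if (cfg$ploidy == "triploid") {
            # drop one of the cn alleles uniformly
            gSub <- g - stats::rbinom(n, 1L, g / pmax(cn, 1L))
            fSub <- gSub / pmax(cn - 1L, 1L)
        } else {
            # duplicate one allele uniformly
            gSub <- g + stats::rbinom(n, 1L, g / pmax(cn, 1L))
            fSub <- gSub / (cn + 1L)
        }
        fEff <- (1 - cfg$mosaicFraction) * f + cfg$mosaicFraction * fSub
    }

    # maternal 46,XX diploid contaminant, genotype drawn independently from
    # the same population AF (no explicit inheritance model)
    gm <- stats::rbinom(n, 2L, af)
    m <- gm / 2

    # depth mixes fetal (cn/basePloidy relative dose) and maternal (XX)
    # contributions; alternate fraction is the depth-weighted mixture
    wFet <- (1 - cfg$maternalFraction) * cn / basePloidy
    wMat <- cfg$maternalFraction
    depthRate <- cfg$meanDepth * (wFet + wMat)
    p <- (wFet * fEff + wMat * m) / (wFet + wMat)

    # symmetric per-read error
    p <- p * (1 - cfg$errorRate) + (1 - p) * cfg$errorRate

    depth <- stats::rpois(n, depthRate)
    altReads <- stats::rbinom(n, depth, p)

    sites <- SNPSites(chrom, start(ps), mcols(ps)$ref, mcols(ps)$alt,
                      refDepth = depth - altReads, altDepth = altReads,
                      panelAF = af, seqinfo = seqinfo(ps))
    truth <- list(ploidy = cfg$ploidy, sex = cfg$sex, cfg = cfg,
                  g = g, cn = cn, fetalFraction = fEff,
                  maternalGenotype = gm, pAlt = p)
    list(sites = sites, panel = panel, truth = truth)
}

#' Simulate a batch of samples
#'
#' Generates \code{nDiploid} diploid then \code{nTriploid} triploid samples
#' against one shared panel, each with a seed derived from \code{seed}.
#' Sexes cycle through the karyotypes allowed for each ploidy. Optionally
#' writes the site tables, panel, chromosome sizes and truth manifest to
#' \code{dir} in the formats the readers consume.
#'
#' @param nDiploid,nTriploid sample counts (\eqn{\ge 0}).
#' @param baseCfg a [simConfig()] supplying everything but ploidy/sex/seed.
#' @param seed integer master seed.
#' @param dir optional output directory.
#' @return list with \code{samples} (named list of \linkS4class{SNPSites}),
#'   \code{panel}, and \code{truth} (\code{data.frame}: sampleId, ploidy,
#'   sex, seed).
#' @export
simulateBatch <- function(nDiploid, nTriploid, baseCfg = simConfig(),
                          seed = 1L, dir = NULL) {
    stopifnot(nDiploid >= 0, nTriploid >= 0)
    nTot <- nDiploid + nTriploid
    panelCfg <- baseCfg
    panelCfg$seed <- as.integer(seed) + 500009L
    panel <- simulatePanel(panelCfg)

    truth <- data.frame(sampleId = character(), ploidy = character(),
                        sex = character(), seed = integer())
    samples <- list()
    dipSex <- c("XX", "XY")
    triSex <- c("XXX", "XXY", "XYY")
    for (i in seq_len(nTot)) {
        ploidy <- if (i <= nDiploid) "diploid" else "triploid"
        sex <- if (ploidy == "diploid") dipSex[1L + (i %% 2L)] else
            triSex[1L + ((i - nDiploid - 1L) %% 3L)]
        cfg <- baseCfg
        cfg$ploidy <- ploidy
        cfg$sex <- sex
        cfg$seed <- as.integer(seed) + i
        id <- sprintf("%s_%03d", ifelse(ploidy == "diploid", "DIP", "TRI"),
                      i)
        samples[[id]] <- simulateSample(cfg, panel = panel)$sites
        truth <- rbind(truth, data.frame(sampleId = id, ploidy = ploidy,
                                         sex = sex, seed = cfg$seed))
    }
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writePanel(panel, file.path(dir, "panel.tsv"),
                   sizesPath = file.path(dir, "chrom.sizes"),
                   gapsPath = file.path(dir, "gaps.bed"))
        for (id in names(samples))
            writeSiteTable(samples[[id]],
                           file.path(dir, paste0(id, ".sites.tsv")))
        utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    list(samples = samples, panel = panel, truth = truth)
}
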