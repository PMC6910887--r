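#' Count mutation ratios in the three intervals
#'
#' Counts how many candidate heterozygous sites have their mutation ratio in
#' each of the closed intervals around 1/3, 1/2 and 2/3. MRs outside all
#' three intervals contribute only to the candidate total. The intervals are
#' disjoint by construction, so no MR can be counted twice.
#'
#' @param x a numeric vector of MR values in \eqn{[0,1]}, or a
#'   \linkS4class{SNPSites} object of candidate heterozygous sites.
#' @param cfg an [intervalConfig()].
#' @param ... unused.
#' @return an \linkS4class{IntervalCounts}.
#' @examples
#' countIntervals(c(0.30, 0.50, 0.66, 0.90))
#' @rdname countIntervals
#' @export
setMethod("countIntervals", "numeric", function(x, cfg = intervalConfig(),
                                                ...) {
    if (length(x) && (any(x < 0) || any(x > 1)))
        stop("mutation ratios must lie in [0, 1]")
    inIv <- function(iv) sum(x >= iv[1] & x <= iv[2])
    new("IntervalCounts",
        nThird = as.integer(inIv(cfg$third)),
        nHalf = as.integer(inIv(cfg$half)),
        nTwoThirds = as.integer(inIv(cfg$twoThirds)),
        nCandidates = length(x))
})

#' @rdname countIntervals
#' @export
setMethod("countIntervals", "SNPSites", function(x, cfg = intervalConfig(),
                                                 ...) {
    countIntervals(mutationRatio(x), cfg)
})

#' Exact quadratic through the three interval points
#'
#' Normalises the interval counts to ordinates summing to one,
#' \eqn{y_i = n_i / (n_{1/3} + n_{1/2} + n_{2/3})}, and interpolates the
#' unique quadratic \eqn{y = ax^2 + bx + c} through \eqn{(1/3, y_1)},
#' \eqn{(1/2, y_2)}, \eqn{(2/3, y_3)}. With the abscissae equally spaced at
#' \eqn{h = 1/6} the coefficients are closed-form:
#' \deqn{a = 18\,(y_1 - 2 y_2 + y_3),\quad b = 3\,(y_3 - y_1) - a,\quad
#'       c = y_2 - a/4 - b/2,}
#' and the symmetry axis is \eqn{-b/(2a)}. No iterative fitting is involved
#' and the residuals at the three abscissae are zero to machine precision.
#' An upward opening (\eqn{a > 0}) indicates triploidy; downward
#' (\eqn{a < 0}) diploidy; \eqn{a = 0} is degenerate and never called
#' diploid.
#'
#' @param x an \linkS4class{IntervalCounts}, or a numeric vector of the
#'   three counts \code{c(nThird, nHalf, nTwoThirds)}.
#' @param ... unused.
#' @return a \linkS4class{ParabolaFit}.
#' @examples
#' fitParabola(c(1, 2, 1))   # symmetric: a < 0, axis exactly 0.5
#' @rdname fitParabola
#' @export
setMethod("fitParabola", "IntervalCounts", function(x, ...) {
    fitParabola(c(x@nThird, x@nHalf, x@nTwoThirds))
})

#' @rdname fitParabola
#' @export
setMethod("fitParabola", "numeric", function(x, ...) {
    stopifnot(length(x) == 3L, all(x >= 0))
    s <- sum(x)
    if (s == 0)
        return(new("ParabolaFit", a = NA_real_, b = NA_real_, c = NA_real_,
                   axis = NA_real_, y = rep(NA_real_, 3),
                   degenerate = TRUE))
    y <- x / s
    a <- 18 * (y[1] - 2 * y[2] + y[3])
    b <- 3 * (y[3] - y[1]) - a
    cc <- y[2] - a / 4 - b / 2
    axis <- if (a != 0) -b / (2 * a) else NA_real_
    new("ParabolaFit", a = a, b = b, c = cc, axis = axis, y = unname(y),
        degenerate = FALSE)
})

#' Evaluate a fitted parabola
#'
#' @param fit a \linkS4class{ParabolaFit}.
#' @param x abscissae.
#' @return \eqn{a x^2 + b x + c}.
#' @export
predictParabola <- function(fit, x) {
    if (fit@degenerate) stop("degenerate fit has no curve")
    fit@a * x^2 + fit@b * x + fit@c
}

setMethod("show", "ParabolaFit", function(object) {
    if (object@degenerate) {
        cat("ParabolaFit: degenerate (all interval counts zero)\n")
    } else {
        cat(sprintf(
            "ParabolaFit: y = %.4f x^2 + %.4f x + %.4f ; axis -b/2a = %s\n",
            object@a, object@b, object@c,
            ifelse(is.na(object@axis), "undefined",
                   sprintf("%.4f", object@axis))))
    }
})

#' The side-to-centre ratio statistic
#'
#' The ratio \eqn{(n_{1/3} + n_{2/3}) / n_{1/2}} of side-interval to
#' centre-interval site counts. Under sum-to-one normalisation the fitted
#' quadratic's leading coefficient satisfies
#' \eqn{a = 18 (r - 2) / (r + 1)}, so \eqn{a > 0 \iff r > 2}: the value 2 is
#' the exact analytic boundary between upward- and downward-opening
#' parabolas, i.e. between the triploid and diploid classes.
#'
#' @param x an \linkS4class{IntervalCounts} (computed), or a
#'   \linkS4class{PloidyCall} (extracted).
#' @param ... unused.
#' @return the ratio, or \code{NA} when \eqn{n_{1/2} = 0}.
#' @examples
#' ratioStatistic(countIntervals(c(0.3, 0.3, 0.5, 0.65)))
#' @rdname ratioStatistic
#' @export
setMethod("ratioStatistic", "IntervalCounts", function(x, ...) {
    if (x@nHalf == 0L) return(NA_real_)
    (x@nThird + x@nTwoThirds) / x@nHalf
})

#' Within-batch Z test of the ratio statistic
#'
#' Auxiliary evidence: each sample's ratio statistic is standardised against
#' the batch, \eqn{z_i = (r_i - \bar r) / s}. With \code{robust = TRUE}
#' (default) the reference mean and SD are computed only from the
#' presumed-diploid samples (ratio \eqn{\le} 2), so triploids cannot mask
#' themselves by inflating the reference; with \code{robust = FALSE} all
#' samples are used.
#'
#' @param ratios numeric vector of per-sample ratio statistics (length
#'   \eqn{\ge} 3; \code{NA}s excluded from the reference).
#' @param robust exclude samples with ratio above 2 from the reference?
#' @return list with \code{z} (numeric, aligned with \code{ratios}) and
#'   \code{stats} (a \linkS4class{BatchStats}).
#' @export
batchZ <- function(ratios, robust = TRUE) {
    if (length(ratios) < 3L)
        stop("batch Z test needs at least 3 samples")
    ref <- ratios[!is.na(ratios)]
    if (robust) ref <- ref[ref <= 2]
    if (length(ref) < 2L)
        stop("fewer than 2 reference samples for the batch Z test")
    m <- mean(ref)
    s <- stats::sd(ref)
    stats <- new("BatchStats", mean = m, sd = s,
                 nReference = length(ref), robust = isTRUE(robust))
    if (s == 0) {
        warning("batch reference SD is zero; Z scores undefined")
        return(list(z = rep(NA_real_, length(ratios)), stats = stats))
    }
    list(z = (ratios - m) / s, stats = stats)
}

setMethod("show", "BatchStats", function(object) {
    cat(sprintf(
        "BatchStats: mean = %.4f, sd = %.4f (n = %d%s)\n",
        object@mean, object@sd, object@nReference,
        if (object@robust) ", robust reference" else ""))
})

#' Classify a sample as diploid or triploid
#'
#' Applies the decision rule: verdict \code{triploid} when the parabola
#' opens upward (\eqn{a > 0}) and the symmetry axis (rounded to
#' \code{cfg$axisDigits} decimals) lies in
#' \code{[axisLo, axisHi]} — or within \code{axisSlack} beyond it, in which
#' case the \code{axis_out_of_range} flag is added; \eqn{a > 0} with the
#' axis beyond the slack gives \code{triploid_low_confidence};
#' \eqn{a < 0} gives \code{diploid}; a degenerate fit, \eqn{a = 0} exactly,
#' an undefined ratio, or fewer than \code{cfg$minSites} candidate sites
#' give \code{inconclusive}. The Z score is auxiliary only: \eqn{|z|} at or
#' above \code{cfg$zFlagThreshold} adds a \code{z_outlier} flag and never
#' overrides the parabola verdict. A ratio within
#' \code{cfg$intermediateBand} of the boundary value 2 adds an
#' \code{intermediate_counts} flag (possible mosaicism or contamination).
#'
#' @param fit a \linkS4class{ParabolaFit}.
#' @param ratio the sample's ratio statistic (may be \code{NA}).
#' @param counts the \linkS4class{IntervalCounts}.
#' @param z optional within-batch Z score.
#' @param sampleId sample identifier.
#' @param cfg a [classifyConfig()].
#' @return a \linkS4class{PloidyCall}.
#' @seealso [callPloidy()] for the full per-sample pipeline.
#' @export
classifyPloidy <- function(fit, ratio, counts, z = NA_real_,
                           sampleId = "sample", cfg = classifyConfig()) {
    flags <- character()
    if (counts@nCandidates < cfg$minSites) flags <- c(flags, "low_sites")
    if (fit@degenerate) flags <- c(flags, "degenerate_fit")
    if (is.na(ratio)) flags <- c(flags, "undefined_ratio")
    if (!is.na(ratio) && abs(ratio - 2) <= cfg$intermediateBand)
        flags <- c(flags, "intermediate_counts")
    if (!is.na(z) && abs(z) >= cfg$zFlagThreshold)
        flags <- c(flags, "z_outlier")
    if (!fit@degenerate && fit@a == 0)
        flags <- c(flags, "degenerate_fit")  # a == 0: axis undefined

    if (fit@degenerate || is.na(ratio) || "low_sites" %in% flags ||
        fit@a == 0) {
        verdict <- "inconclusive"
    } else if (fit@a < 0) {
        verdict <- "diploid"
    } else {
        ax <- round(fit@axis, cfg$axisDigits)
        if (ax >= cfg$axisLo && ax <= cfg$axisHi) {
            verdict <- "triploid"
        } else if (ax >= cfg$axisLo - cfg$axisSlack &&
                   ax <= cfg$axisHi + cfg$axisSlack) {
            verdict <- "triploid"
            flags <- c(flags, "axis_out_of_range")
        } else {
            verdict <- "triploid_low_confidence"
            flags <- c(flags, "axis_out_of_range")
        }
    }
    new("PloidyCall", sampleId = sampleId, ratio = as.numeric(ratio),
        fit = fit, z = as.numeric(z), verdict = verdict,
        flags = unique(flags), counts = counts)
}

#' Full per-sample ploidy pipeline
#'
#' Filters the input sites against the panel, selects observationally
#' heterozygous candidates, computes mutation ratios and interval counts,
#' fits the exact quadratic, and classifies. Run [callPloidyBatch()] to add
#' the within-batch Z test.
#'
#' Sex chromosomes are excluded from the MR analysis by default: the X
#' heterozygote MR distribution depends on the sex karyotype (hemizygous in
#' XY and XYY, disomic — diploid-like — in XXY), so X sites would dilute the
#' triploid signal of XXY samples while contributing nothing in XY/XYY.
#' Autosomal sites carry the ploidy information uniformly.
#'
#' @param sites a \linkS4class{SNPSites} object (all parsed sites).
#' @param panel a \linkS4class{SNPPanel}.
#' @param sampleId sample identifier.
#' @param filterCfg a [filterConfig()].
#' @param intervalCfg an [intervalConfig()].
#' @param classifyCfg a [classifyConfig()].
#' @param excludeChroms chromosomes left out of the MR analysis (default
#'   the sex chromosomes).
#' @return a \linkS4class{PloidyCall}.
#' @export
callPloidy <- function(sites, panel, sampleId = "sample",
                       filterCfg = filterConfig(),
                       intervalCfg = intervalConfig(),
                       classifyCfg = classifyConfig(),
                       excludeChroms = c("chrX", "chrY", "X", "Y")) {
    if (length(excludeChroms))
        sites <- sites[!as.character(seqnames(sites)) %in% excludeChroms]
    kept <- filterSites(sites, panel, filterCfg)
    het <- selectHeterozygous(kept, filterCfg)
    counts <- countIntervals(het, intervalCfg)
    fit <- fitParabola(counts)
    classifyPloidy(fit, ratioStatistic(counts), counts,
                   sampleId = sampleId, cfg = classifyCfg)
}

#' Batch ploidy pipeline with Z test
#'
#' Runs [callPloidy()] on every sample, computes the within-batch Z test on
#' the ratio statistics, and re-issues each call with its Z score attached.
#'
#' @param samples named list of \linkS4class{SNPSites} objects.
#' @param panel a \linkS4class{SNPPanel}.
#' @param robust passed to [batchZ()].
#' @inheritParams callPloidy
#' @return list with \code{calls} (named list of \linkS4class{PloidyCall}),
#'   \code{stats} (a \linkS4class{BatchStats} or \code{NULL} when the batch
#'   is too small), and \code{table} (per-sample \code{data.frame}).
#' @export
callPloidyBatch <- function(samples, panel,
                            filterCfg = filterConfig(),
                            intervalCfg = intervalConfig(),
                            classifyCfg = classifyConfig(),
                            robust = TRUE,
                            excludeChroms = c("chrX", "chrY", "X", "Y")) {
    if (is.null(names(samples)))
        names(samples) <- paste0("sample_", seq_along(samples))
    calls <- lapply(names(samples), function(id)
        callPloidy(samples[[id]], panel, sampleId = id,
                   filterCfg = filterCfg, intervalCfg = intervalCfg,
                   classifyCfg = classifyCfg,
                   excludeChroms = excludeChroms))
    names(calls) <- names(samples)
    ratios <- vapply(calls, function(cl) cl@ratio, numeric(1))
    stats <- NULL
    if (length(calls) >= 3L) {
        bz <- batchZ(ratios, robust = robust)
        stats <- bz$stats
        calls <- lapply(seq_along(calls), function(i)
            classifyPloidy(calls[[i]]@fit, calls[[i]]@ratio,
                           calls[[i]]@counts, z = bz$z[i],
                           sampleId = calls[[i]]@sampleId,
                           cfg = classifyCfg))
        names(calls) <- names(samples)
    }
    list(calls = calls, stats = stats, table = ploidyTable(calls))
}

#' Tabulate ploidy calls
#'
#' @param calls list of \linkS4class{PloidyCall} objects.
#' @return a \code{data.frame} with one row per sample.
#' @export
ploidyTable <- function(calls) {
    data.frame(
        sampleId = vapply(calls, sampleId, character(1)),
        ratio = vapply(calls, function(cl) cl@ratio, numeric(1)),
        a = vapply(calls, function(cl) cl@fit@a, numeric(1)),
        axis = vapply(calls, function(cl) cl@fit@axis, numeric(1)),
        z = vapply(calls, zScore, numeric(1)),
        nCandidates = vapply(calls,
                             function(cl) cl@counts@nCandidates,
                             integer(1)),
        verdict = vapply(calls, verdict, character(1)),
        flags = vapply(calls, function(cl)
            paste(qcFlags(cl), collapse = ";"), character(1)),
        row.names = NULL)
}

#' Accessors for PloidyCall
#'
#' @param x a \linkS4class{PloidyCall}.
#' @name PloidyCall-accessors
NULL

#' @rdname PloidyCall-accessors
#' @export
setMethod("verdict", "PloidyCall", function(x) x@verdict)

#' @rdname PloidyCall-accessors
#' @export
setMethod("qcFlags", "PloidyCall", function(x) x@flags)

#' @rdname PloidyCall-accessors
#' @export
setMethod("zScore", "PloidyCall", function(x) x@z)

#' @rdname PloidyCall-accessors
#' @export
setMethod("sampleId", "PloidyCall", function(x) x@sampleId)

#' @rdname PloidyCall-accessors
#' @export
setMethod("ratioStatistic", "PloidyCall", function(x, ...) x@ratio)

setMethod("show", "PloidyCall", function(object) {
    cat("PloidyCall for", object@sampleId, "\n")
    cat("  verdict:", object@verdict, "\n")
    cat(sprintf("  ratio (1/3+2/3)/(1/2): %s\n",
                ifelse(is.na(object@ratio), "undefined",
                       sprintf("%.4f", object@ratio))))
    if (!object@fit@degenerate)
        cat(sprintf("  parabola a = %.4f, axis = %s\n", object@fit@a,
                    ifelse(is.na(object@fit@axis), "undefined",
                           sprintf("%.4f", object@fit@axis))))
    cat(sprintf("  z = %s; candidate het sites = %d\n",
                ifelse(is.na(object@z), "NA", sprintf("%.2f", object@z)),
                object@counts@nCandidates))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
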