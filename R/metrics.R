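#' Confusion-matrix performance metrics
#'
#' With true positives \eqn{a}, false positives \eqn{b}, false negatives
#' \eqn{c} and true negatives \eqn{d}:
#' sensitivity \eqn{= a/(a+c) \times 100\%}, specificity
#' \eqn{= d/(b+d) \times 100\%}, accuracy
#' \eqn{= (a+d)/(a+b+c+d) \times 100\%}, each reported to two decimals.
#' A metric whose denominator is zero is reported as \code{NA} (undefined),
#' never as 0.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return named numeric vector \code{c(sensitivity, specificity,
#'   accuracy)} in percent.
#' @examples
#' confusionMetrics(8, 1, 0, 212)
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
    stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
    total <- tp + fp + fn + tn
    if (total == 0) stop("empty confusion matrix")
    pct <- function(num, den) if (den == 0) NA_real_ else
        round(100 * num / den, 2)
    c(sensitivity = pct(tp, tp + fn),
      specificity = pct(tn, fp + tn),
      accuracy = pct(tp + tn, total))
}

#' Join ploidy calls to simulation truth
#'
#' Cross-tabulates calls against truth: \code{triploid} and
#' \code{triploid_low_confidence} count as positive calls;
#' \code{inconclusive} samples are excluded from the confusion matrix
#' (mirroring clinical retest practice) and reported separately.
#'
#' @param calls list of \linkS4class{PloidyCall} objects, or a
#'   \code{data.frame} from [ploidyTable()].
#' @param truth \code{data.frame} with columns \code{sampleId} and
#'   \code{ploidy} (\code{"diploid"}/\code{"triploid"}).
#' @return list with \code{counts} (named vector tp/fp/fn/tn),
#'   \code{metrics} (from [confusionMetrics()]), \code{nInconclusive}, and
#'   \code{join} (per-sample \code{data.frame}).
#' @export
evaluateBatch <- function(calls, truth) {
    tab <- if (is.data.frame(calls)) calls else ploidyTable(calls)
    missing <- setdiff(tab$sampleId, truth$sampleId)
    if (length(missing))
        stop("no truth entry for sample(s): ",
             paste(missing, collapse = ", "))
    join <- merge(tab, truth[, c("sampleId", "ploidy")], by = "sampleId",
                  sort = TRUE)
    positive <- join$verdict %in% c("triploid", "triploid_low_confidence")
    inconclusive <- join$verdict == "inconclusive"
    isTri <- join$ploidy == "triploid"
    counts <- c(tp = sum(positive & isTri & !inconclusive),
                fp = sum(positive & !isTri & !inconclusive),
                fn = sum(!positive & isTri & !inconclusive),
                tn = sum(!positive & !isTri & !inconclusive))
    list(counts = counts,
         metrics = confusionMetrics(counts[["tp"]], counts[["fp"]],
                                    counts[["fn"]], counts[["tn"]]),
         nInconclusive = sum(inconclusive),
         join = join)
}
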