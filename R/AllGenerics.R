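#' @rdname SNPSites-accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname SNPSites-accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname SNPSites-accessors
#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))

#' @rdname SNPSites-accessors
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))

#' @rdname SNPSites-accessors
#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))

#' @rdname SNPSites-accessors
#' @export
setGeneric("panelAF", function(x) standardGeneric("panelAF"))

#' @rdname mutationRatio
#' @export
setGeneric("mutationRatio", function(x, ...) standardGeneric("mutationRatio"))

#' @rdname countIntervals
#' @export
setGeneric("countIntervals", function(x, cfg = intervalConfig(), ...)
    standardGeneric("countIntervals"))

#' @rdname fitParabola
#' @export
setGeneric("fitParabola", function(x, ...) standardGeneric("fitParabola"))

#' @rdname ratioStatistic
#' @export
setGeneric("ratioStatistic", function(x, ...)
    standardGeneric("ratioStatistic"))

#' @rdname PloidyCall-accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname PloidyCall-accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname PloidyCall-accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname PloidyCall-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SNPPanel
#' @export
setGeneric("panelSites", function(x) standardGeneric("panelSites"))

#' @rdname SNPPanel
#' @export
setGeneric("panelGaps", function(x) standardGeneric("panelGaps"))
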