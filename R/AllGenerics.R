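#' @rdname DigestSummary-class
#' @param x a ddGBStools object.
#' @export
setGeneric("captureFraction", function(x) standardGeneric("captureFraction"))

#' @rdname DigestSummary-class
#' @export
setGeneric("capturedBp", function(x) standardGeneric("capturedBp"))

#' @rdname DigestSummary-class
#' @export
setGeneric("endClassCounts", function(x) standardGeneric("endClassCounts"))

#' @rdname DigestSummary-class
#' @export
setGeneric("lengthHistogram", function(x) standardGeneric("lengthHistogram"))

#' @rdname SizeWindow-class
#' @param x a [SizeWindow-class].
#' @export
setGeneric("insertWindow", function(x) standardGeneric("insertWindow"))

#' @rdname GenotypeCalls-class
#' @param x a [GenotypeCalls-class].
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("siteMAF", function(x) standardGeneric("siteMAF"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("siteCallRate", function(x) standardGeneric("siteCallRate"))

#' @rdname DemuxResult-class
#' @param x a [DemuxResult-class].
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' Per-site and per-sample report accessors
#'
#' @param x a report object ([MendelReport-class],
#'   [ConcordanceReport-class], ...).
#' @return a data.frame.
#' @export
setGeneric("perSite", function(x) standardGeneric("perSite"))

#' @rdname perSite
#' @export
setGeneric("perSample", function(x) standardGeneric("perSample"))
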