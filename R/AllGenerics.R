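#' @rdname GuideLibrary-accessors
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("spacers", function(x) standardGeneric("spacers"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("nGuides", function(x) standardGeneric("nGuides"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("guidesPerGene", function(x) standardGeneric("guidesPerGene"))

#' @rdname GuideLibrary-accessors
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))

#' @rdname SampleCounts-accessors
#' @export
setGeneric("guideCounts", function(x) standardGeneric("guideCounts"))

#' @rdname SampleCounts-accessors
#' @export
setGeneric("nUnmapped", function(x) standardGeneric("nUnmapped"))

#' @rdname SampleCounts-accessors
#' @export
setGeneric("nTotalReads", function(x) standardGeneric("nTotalReads"))

#' @rdname GuideComparison-accessors
#' @export
setGeneric("overallMean", function(x) standardGeneric("overallMean"))

#' @rdname GuideComparison-accessors
#' @export
setGeneric("replicateValues", function(x) standardGeneric("replicateValues"))

#' @rdname GuideComparison-accessors
#' @export
setGeneric("experimentMeans", function(x) standardGeneric("experimentMeans"))
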