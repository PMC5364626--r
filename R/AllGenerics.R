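#' @rdname PeakSet-class
#' @param object,x A `PeakSet`, `GeneCatalog` or `SignalTrack`.
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname PeakSet-class
#' @export
setGeneric("summits", function(x) standardGeneric("summits"))

#' @rdname PeakSet-class
#' @export
setGeneric("peakScores", function(x) standardGeneric("peakScores"))

#' @rdname PeakSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("geneClasses", function(x) standardGeneric("geneClasses"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @rdname SignalTrack-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname SignalTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Total size of a consensus shortlist
#'
#' The size of the shortlisted core regulome: the reproducible set plus the
#' opposite-direction rescued set (always disjoint, so the total is the sum
#' of the two sizes).
#'
#' @param x A [CoreRegulomeResult-class].
#' @return Integer count of shortlisted genes.
#' @export
setGeneric("regulomeTotal", function(x) standardGeneric("regulomeTotal"))
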