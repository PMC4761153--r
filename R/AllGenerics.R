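#' @include AllClasses.R
NULL

#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @export
setGeneric("siteClass", function(x) standardGeneric("siteClass"))
#' @export
setGeneric("segSites", function(x) standardGeneric("segSites"))
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))

#' @export
setGeneric("wattersonTheta", function(x, ...) standardGeneric("wattersonTheta"))
#' @export
setGeneric("nucleotideDiversity",
           function(x, ...) standardGeneric("nucleotideDiversity"))
#' @export
setGeneric("tajimaD", function(x, ...) standardGeneric("tajimaD"))
#' @export
setGeneric("fuLiDStar", function(x, ...) standardGeneric("fuLiDStar"))

#' @export
setGeneric("mkCounts", function(x) standardGeneric("mkCounts"))
#' @export
setGeneric("neutralityIndex", function(x) standardGeneric("neutralityIndex"))
#' @export
setGeneric("alphaAdaptive", function(x) standardGeneric("alphaAdaptive"))

#' @export
setGeneric("geneSummary", function(x) standardGeneric("geneSummary"))
#' @export
setGeneric("snvRecords", function(x) standardGeneric("snvRecords"))
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("sweepStats", function(x) standardGeneric("sweepStats"))
#' @export
setGeneric("sweepSummary", function(x) standardGeneric("sweepSummary"))
#' @export
setGeneric("sweepMeta", function(x) standardGeneric("sweepMeta"))
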