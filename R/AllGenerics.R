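#' @export
setGeneric("mz", function(object, ...) standardGeneric("mz"))

#' @export
setGeneric("intensity", function(object, ...) standardGeneric("intensity"))

#' @export
setGeneric("stage", function(object, ...) standardGeneric("stage"))

#' @export
setGeneric("spectrumId", function(object, ...) standardGeneric("spectrumId"))

#' @export
setGeneric("totalSpectra", function(object, ...) standardGeneric("totalSpectra"))

#' @export
setGeneric("totalSamples", function(object, ...) standardGeneric("totalSamples"))

#' @export
setGeneric("designCells", function(object, ...) standardGeneric("designCells"))

#' @export
setGeneric("peakMz", function(object, ...) standardGeneric("peakMz"))

#' @export
setGeneric("peakIndex", function(object, ...) standardGeneric("peakIndex"))

#' @export
setGeneric("profileLevel", function(object, ...) standardGeneric("profileLevel"))

#' @export
setGeneric("transformLog", function(object, ...) standardGeneric("transformLog"))

#' @export
setGeneric("nodeTable", function(object, ...) standardGeneric("nodeTable"))

#' @export
setGeneric("nodeMembers", function(object, ...) standardGeneric("nodeMembers"))
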