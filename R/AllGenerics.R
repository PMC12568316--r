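#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @export
setGeneric("binning", function(x) standardGeneric("binning"))

#' @export
setGeneric("rtAxis", function(x) standardGeneric("rtAxis"))

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @export
setGeneric("goldenCoords", function(x) standardGeneric("goldenCoords"))

#' @export
setGeneric("meanEntropies", function(x) standardGeneric("meanEntropies"))

#' @export
setGeneric("numPatches", function(x) standardGeneric("numPatches"))

#' @export
setGeneric("imageTensor", function(x) standardGeneric("imageTensor"))
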