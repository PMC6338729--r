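#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib spatprot, .registration = TRUE
NULL

#' @export
setGeneric("profileMatrix", function(object, ...) standardGeneric("profileMatrix"))

#' @export
setGeneric("channelInfo", function(object, ...) standardGeneric("channelInfo"))

#' @export
setGeneric("featureInfo", function(object, ...) standardGeneric("featureInfo"))

#' @export
setGeneric("markerLabels", function(object, ...) standardGeneric("markerLabels"))

#' @export
setGeneric("markerClasses", function(object, ...) standardGeneric("markerClasses"))

#' @export
setGeneric("sumNormalizeRows", function(object, ...) standardGeneric("sumNormalizeRows"))

#' @export
setGeneric("scoreMatrix", function(object, ...) standardGeneric("scoreMatrix"))

#' @export
setGeneric("assignedClass", function(object, ...) standardGeneric("assignedClass"))

#' @export
setGeneric("finalLabel", function(object, ...) standardGeneric("finalLabel"))

#' @export
setGeneric("classThresholds", function(object, ...) standardGeneric("classThresholds"))

#' @export
setGeneric("qsepRaw", function(object, ...) standardGeneric("qsepRaw"))

#' @export
setGeneric("qsepNormalised", function(object, ...) standardGeneric("qsepNormalised"))

#' @export
setGeneric("thetaWeights", function(object, ...) standardGeneric("thetaWeights"))

#' @export
setGeneric("medianTheta", function(object, ...) standardGeneric("medianTheta"))
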