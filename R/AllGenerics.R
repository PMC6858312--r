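#' @include AllClasses.R
NULL

#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))

#' @export
setGeneric("featureGroups", function(x, ...) standardGeneric("featureGroups"))

#' @export
setGeneric("nFeatures", function(x, ...) standardGeneric("nFeatures"))

#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @export
setGeneric("variantRecords", function(x, ...) standardGeneric("variantRecords"))

#' @export
setGeneric("geneSymbols", function(x, ...) standardGeneric("geneSymbols"))

#' @export
setGeneric("featureSchema", function(x, ...) standardGeneric("featureSchema"))

#' @export
setGeneric("sampleLabels", function(x, ...) standardGeneric("sampleLabels"))

#' @export
setGeneric("selectedFeatures", function(x, ...) standardGeneric("selectedFeatures"))

#' @export
setGeneric("selectionScores", function(x, ...) standardGeneric("selectionScores"))

#' @export
setGeneric("predictProba", function(object, X, ...) standardGeneric("predictProba"))

#' @export
setGeneric("classLevels", function(x, ...) standardGeneric("classLevels"))

#' @export
setGeneric("cvPredictions", function(x, ...) standardGeneric("cvPredictions"))

#' @export
setGeneric("overallAccuracy", function(x, ...) standardGeneric("overallAccuracy"))

#' @export
setGeneric("perClassMetrics", function(x, ...) standardGeneric("perClassMetrics"))

#' @export
setGeneric("foldIndices", function(x, ...) standardGeneric("foldIndices"))
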