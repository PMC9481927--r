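#' @name cortexomics-generics
#' @title Generics defined by cortexomics
#' @description S4 generics for accessing and transforming
#'   [SpectralCountSet-class] objects and for contour/timing metrics.
#' @param x,object a cortexomics object.
#' @param ... passed to methods.
NULL

#' @rdname cortexomics-generics
#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @rdname cortexomics-generics
#' @export
setGeneric("normalisedCounts", function(x) standardGeneric("normalisedCounts"))

#' @rdname cortexomics-generics
#' @export
setGeneric("uniquePeptides", function(x) standardGeneric("uniquePeptides"))

#' @rdname cortexomics-generics
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname cortexomics-generics
#' @export
setGeneric("replicateConditions",
           function(x) standardGeneric("replicateConditions"))

#' @rdname cortexomics-generics
#' @export
setGeneric("replicateTotals", function(x) standardGeneric("replicateTotals"))

#' @rdname cortexomics-generics
#' @export
setGeneric("referenceReplicate",
           function(x) standardGeneric("referenceReplicate"))

#' @rdname cortexomics-generics
#' @export
setGeneric("isNormalised", function(x) standardGeneric("isNormalised"))

#' @rdname cortexomics-generics
#' @param reference column name of the reference replicate.
#' @export
setGeneric("normaliseToReference", function(x, reference = "interphase_1")
  standardGeneric("normaliseToReference"))

#' @rdname cortexomics-generics
#' @param assay which assay to average (`"normalised"` or `"counts"`).
#' @export
setGeneric("conditionMeans", function(x, assay = "normalised")
  standardGeneric("conditionMeans"))

#' @rdname cortexomics-generics
#' @param criteria a [SelectionCriteria-class] object.
#' @export
setGeneric("selectProteins", function(x, criteria = SelectionCriteria())
  standardGeneric("selectProteins"))

#' @rdname cortexomics-generics
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname cortexomics-generics
#' @export
setGeneric("polygonArea", function(x) standardGeneric("polygonArea"))

#' @rdname cortexomics-generics
#' @export
setGeneric("polygonPerimeter",
           function(x) standardGeneric("polygonPerimeter"))

#' @rdname cortexomics-generics
#' @export
setGeneric("circularity", function(x) standardGeneric("circularity"))

#' @rdname cortexomics-generics
#' @export
setGeneric("aspectRatio", function(x) standardGeneric("aspectRatio"))

#' @rdname cortexomics-generics
#' @export
setGeneric("roundingTime", function(x) standardGeneric("roundingTime"))

#' @rdname cortexomics-generics
#' @export
setGeneric("ingressionTime", function(x) standardGeneric("ingressionTime"))
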