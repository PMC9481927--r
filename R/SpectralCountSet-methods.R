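# Accessors and show methods for SpectralCountSet.

#' @describeIn SpectralCountSet-class raw integer spectral counts
#'   (proteins x replicates).
#' @param x,object a `SpectralCountSet`.
#' @export
setMethod("spectralCounts", "SpectralCountSet", function(x) {
  SummarizedExperiment::assay(x, "counts")
})

#' @describeIn SpectralCountSet-class normalised counts; errors if
#'   [normaliseToReference()] has not been applied.
#' @export
setMethod("normalisedCounts", "SpectralCountSet", function(x) {
  if (!isNormalised(x))
    degenerateError("no 'normalised' assay: run normaliseToReference() first")
  SummarizedExperiment::assay(x, "normalised")
})

#' @describeIn SpectralCountSet-class `TRUE` once a normalised assay is
#'   present.
#' @export
setMethod("isNormalised", "SpectralCountSet", function(x) {
  "normalised" %in% SummarizedExperiment::assayNames(x)
})

#' @describeIn SpectralCountSet-class dataset-wide unique peptide count
#'   per protein, named by accession.
#' @export
setMethod("uniquePeptides", "SpectralCountSet", function(x) {
  setNames(SummarizedExperiment::rowData(x)$unique_peptides, rownames(x))
})

#' @describeIn SpectralCountSet-class gene symbol per protein, named by
#'   accession.
#' @export
setMethod("geneSymbols", "SpectralCountSet", function(x) {
  setNames(as.character(SummarizedExperiment::rowData(x)$gene_symbol),
           rownames(x))
})

#' @describeIn SpectralCountSet-class condition of each replicate column,
#'   named by column.
#' @export
setMethod("replicateConditions", "SpectralCountSet", function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$condition),
           colnames(x))
})

#' @describeIn SpectralCountSet-class reference replicate column name
#'   recorded by [normaliseToReference()] (`NA` before normalisation).
#' @export
setMethod("referenceReplicate", "SpectralCountSet", function(x) {
  ref <- S4Vectors::metadata(x)$reference_replicate
  if (is.null(ref)) NA_character_ else ref
})

#' @describeIn SpectralCountSet-class compact display.
#' @export
setMethod("show", "SpectralCountSet", function(object) {
  cond <- replicateConditions(object)
  cat(sprintf("SpectralCountSet: %d proteins x %d replicates (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s n=%d", CONDITIONS,
                            tabulate(factor(cond, CONDITIONS), 2L)),
                    collapse = ", ")))
  if (isNormalised(object))
    cat(sprintf("  normalised to reference '%s' (total %.0f)\n",
                referenceReplicate(object),
                S4Vectors::metadata(object)$reference_total))
  callNextMethod()
})

#' @describeIn DifferentialResults-class compact display.
#' @param object a `DifferentialResults`.
#' @export
setMethod("show", "DifferentialResults", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf(
    "DifferentialResults: %d proteins, %d significant (one-tailed p < %g, tail '%s')\n",
    nrow(object), sum(object$significant), md$alpha, md$tail))
  callNextMethod()
})

#' @describeIn CandidateReport-class compact display with subset counts.
#' @param object a `CandidateReport`.
#' @export
setMethod("show", "CandidateReport", function(object) {
  s <- S4Vectors::metadata(object)$summary
  cat(sprintf(paste0(
    "CandidateReport: %d proteins | significant %d | actin-related %d ",
    "(significant %d) | screen tested %d, hits %d | dual evidence %d\n"),
    nrow(object), s["significant"], s["actin_related"],
    s["significant_actin_related"], s["screen_tested"], s["screen_hit"],
    s["dual_evidence"]))
  callNextMethod()
})

#' @describeIn CellContour-class vertex matrix accessor.
#' @param x a `CellContour`.
#' @export
setMethod("vertices", "CellContour", function(x) x@vertices)

#' @describeIn CellContour-class compact display.
#' @export
setMethod("show", "CellContour", function(object) {
  cat(sprintf("CellContour: %d vertices, frame %d\n",
              nrow(object@vertices), object@frameIndex))
})

#' @describeIn DivisionEvents-class compact display with derived times.
#' @export
setMethod("show", "DivisionEvents", function(object) {
  cat(sprintf(paste0("DivisionEvents: frames %d -> %d -> %d -> %d ",
                     "@ %.3g min/frame (rounding %.3g min, ingression %.3g min)\n"),
              object@roundingOnsetFrame, object@roundingCompleteFrame,
              object@metaphaseEndFrame, object@ingressionEndFrame,
              object@frameIntervalMin,
              roundingTime(object), ingressionTime(object)))
})

#' @describeIn AnnotationSets-class compact display.
#' @export
setMethod("show", "AnnotationSets", function(object) {
  cat(sprintf("AnnotationSets: %d actin-related, %d screen-tested, %d screen hits\n",
              length(object@actinRelated), length(object@screenTested),
              length(object@screenHit)))
})
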