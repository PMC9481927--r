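#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment assay assayNames rowData colData
NULL

CONDITIONS <- c("interphase", "mitosis")

#' SpectralCountSet: protein-level spectral counts across replicates
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one protein per
#' row and one replicate per column. The `"counts"` assay stores raw
#' integer spectral counts; after [normaliseToReference()] a
#' `"normalised"` assay of reference-scaled real counts is added.
#' Row metadata carries the gene symbol and the dataset-wide unique
#' peptide count per protein; column metadata carries the condition
#' (`interphase` or `mitosis`) and the replicate index.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [SpectralCountSet()] for construction,
#'   [spectralCounts()], [normalisedCounts()], [uniquePeptides()],
#'   [geneSymbols()] for access.
#' @export
setClass("SpectralCountSet", contains = "SummarizedExperiment")

setValidity("SpectralCountSet", function(object) {
  msg <- character()
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "raw counts must be finite non-negative integers")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyNA(rn) || any(rn == ""))
    msg <- c(msg, "accessions (rownames) must be non-empty")
  else if (anyDuplicated(rn)) {
    dup <- unique(rn[duplicated(rn)])
    msg <- c(msg, paste0("duplicate accessions: ",
                         paste(utils::head(dup, 5L), collapse = ", ")))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene_symbol", "unique_peptides") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'gene_symbol' and 'unique_peptides'")
  else {
    up <- rd$unique_peptides
    if (any(!is.finite(up)) || any(up < 0) || any(up != round(up)))
      msg <- c(msg, "unique_peptides must be non-negative integers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'condition' and 'replicate'")
  else {
    cond <- as.character(cd$condition)
    if (!all(cond %in% CONDITIONS))
      msg <- c(msg, sprintf("conditions must be one of: %s",
                            paste(CONDITIONS, collapse = ", ")))
    if (anyDuplicated(paste(cond, cd$replicate)))
      msg <- c(msg, "(condition, replicate) labels must be unique")
    if (length(unique(cond)) < 2L)
      msg <- c(msg, "at least one replicate per condition is required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralCountSet
#'
#' @param counts integer matrix, proteins x replicates. Rownames are the
#'   protein accessions.
#' @param condition character/factor of `"interphase"`/`"mitosis"`, one
#'   per column of `counts`.
#' @param replicate integer replicate index within condition (defaults to
#'   1..n within each condition).
#' @param geneSymbol character, one gene symbol per protein.
#' @param uniquePeptides integer, dataset-wide unique peptide count per
#'   protein.
#' @return A [SpectralCountSet-class] object. Columns are named
#'   `<condition>_<replicate>`.
#' @examples
#' m <- matrix(c(5L, 1L, 7L, 2L), 2, 2,
#'             dimnames = list(c("P1", "P2"), NULL))
#' scs <- SpectralCountSet(m, condition = c("interphase", "mitosis"),
#'                         geneSymbol = c("MYH9", "SEPT9"),
#'                         uniquePeptides = c(10L, 4L))
#' spectralCounts(scs)
#' @export
SpectralCountSet <- function(counts, condition, replicate = NULL,
                             geneSymbol, uniquePeptides) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    formatError("'condition' must have one entry per count column")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  colnames(counts) <- paste0(condition, "_", replicate)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      gene_symbol = as.character(geneSymbol),
      unique_peptides = as.integer(uniquePeptides),
      row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(
      condition = factor(condition, levels = CONDITIONS),
      replicate = replicate,
      row.names = colnames(counts)))
  new("SpectralCountSet", se)
}

#' Per-protein differential testing results
#'
#' A `DataFrame` subclass produced by [volcanoTable()], one row per
#' tested protein, with per-condition means, log2 enrichment
#' (positive = mitosis-enriched), the Student t statistic (oriented
#' mitosis minus interphase), degrees of freedom, one-tailed p-value,
#' -log10 p, the significance flag at the chosen alpha, BH-adjusted
#' q-values and a degenerate-variance flag. `metadata()` records
#' `alpha`, `tail` and the pseudocount used.
#'
#' @export
setClass("DifferentialResults", contains = "DFrame")

#' Candidate annotation report
#'
#' A `DataFrame` subclass produced by [annotateResults()]: the
#' differential results augmented with `actin_related`, `screen_tested`,
#' `screen_hit` and `dual_evidence` flags. `metadata()$summary` holds the
#' subset counts (significant, actin-related, significant actin-related,
#' screen tested/hits among results, dual evidence) plus the number of
#' annotation identifiers that matched no result.
#'
#' @export
setClass("CandidateReport", contains = "DifferentialResults")

#' Curated annotation sets for candidate ranking
#'
#' Three symbol sets: an actin-related set (curated actin interactome
#' plus manual additions), the proteins tested in a mechanical screen of
#' mitotic rounding force, and the screen's significant hits (a subset
#' of the tested set).
#'
#' @slot actinRelated character set of gene symbols.
#' @slot screenTested character set of gene symbols.
#' @slot screenHit character set of gene symbols; must be contained in
#'   `screenTested`.
#' @export
setClass("AnnotationSets",
         representation(actinRelated = "character",
                        screenTested = "character",
                        screenHit = "character"))

setValidity("AnnotationSets", function(object) {
  bad <- setdiff(object@screenHit, object@screenTested)
  if (length(bad))
    paste0("screen hits not among screen-tested proteins: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  else TRUE
})

#' @rdname AnnotationSets-class
#' @param actinRelated,screenTested,screenHit character vectors of gene
#'   symbols (de-duplicated on construction).
#' @return An `AnnotationSets` object.
#' @export
AnnotationSets <- function(actinRelated = character(),
                           screenTested = character(),
                           screenHit = character()) {
  obj <- new("AnnotationSets",
             actinRelated = unique(as.character(actinRelated)),
             screenTested = unique(as.character(screenTested)),
             screenHit = unique(as.character(screenHit)))
  validObject(obj)
  obj
}

#' Selection criteria for the protein funnel
#'
#' Thresholds for the reliability funnel: a protein is retained when its
#' unique peptide count and its mean normalised spectral count in every
#' condition meet the thresholds. Thresholds are inclusive by default
#' (at least two unique peptides, mean count two or higher); set
#' `strictInequality = TRUE` for the strict (> threshold) reading.
#'
#' @slot minUniquePeptides numeric threshold on unique peptides (default 2).
#' @slot minMeanNormalised numeric threshold on the per-condition mean
#'   normalised count (default 2).
#' @slot requireBothConditions logical; when `TRUE` (default) the mean
#'   threshold must hold in every condition, enforcing dual-condition
#'   presence.
#' @slot strictInequality logical; `FALSE` (default) uses `>=`.
#' @export
setClass("SelectionCriteria",
         representation(minUniquePeptides = "numeric",
                        minMeanNormalised = "numeric",
                        requireBothConditions = "logical",
                        strictInequality = "logical"))

setValidity("SelectionCriteria", function(object) {
  if (object@minUniquePeptides < 0 || object@minMeanNormalised < 0)
    "thresholds must be >= 0"
  else TRUE
})

#' @rdname SelectionCriteria-class
#' @param minUniquePeptides,minMeanNormalised,requireBothConditions,strictInequality
#'   see slot documentation.
#' @return A `SelectionCriteria` object.
#' @export
SelectionCriteria <- function(minUniquePeptides = 2,
                              minMeanNormalised = 2,
                              requireBothConditions = TRUE,
                              strictInequality = FALSE) {
  checkScalar(minUniquePeptides, "minUniquePeptides", lower = 0)
  checkScalar(minMeanNormalised, "minMeanNormalised", lower = 0)
  obj <- new("SelectionCriteria",
             minUniquePeptides = minUniquePeptides,
             minMeanNormalised = minMeanNormalised,
             requireBothConditions = isTRUE(requireBothConditions),
             strictInequality = isTRUE(strictInequality))
  validObject(obj)
  obj
}

#' Polygonal cell contour
#'
#' An ordered list of 2-D vertices (micrometres) tracing a cell outline
#' in a single movie frame, as produced by manual segmentation of the
#' cellular midplane. Metric operations require a simple
#' (non-self-intersecting) polygon.
#'
#' @slot vertices numeric matrix, n x 2, columns `x_um`, `y_um`.
#' @slot frameIndex integer frame the contour was drawn on.
#' @export
setClass("CellContour",
         representation(vertices = "matrix", frameIndex = "integer"))

setValidity("CellContour", function(object) {
  v <- object@vertices
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 2L)
    msg <- c(msg, "vertices must be a numeric n x 2 matrix")
  else {
    if (nrow(v) < 3L) msg <- c(msg, "a contour needs at least 3 vertices")
    if (any(!is.finite(v))) msg <- c(msg, "vertex coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CellContour-class
#' @param vertices n x 2 numeric matrix of vertex coordinates in µm.
#' @param frameIndex integer frame index (default 0).
#' @return A `CellContour` object.
#' @export
CellContour <- function(vertices, frameIndex = 0L) {
  vertices <- as.matrix(vertices)
  colnames(vertices) <- c("x_um", "y_um")
  obj <- new("CellContour", vertices = vertices,
             frameIndex = as.integer(frameIndex))
  validObject(obj)
  obj
}

#' Annotated division-event frames
#'
#' Frame indices of the four division landmarks scored from timelapse
#' imaging — onset of rounding (first frame with edge retraction),
#' completion of rounding (first fully round frame; set to the end of
#' metaphase when rounding continues throughout metaphase), end of
#' metaphase (last frame with aligned chromosomes) and end of furrow
#' ingression — together with the acquisition frame interval in minutes.
#'
#' @slot roundingOnsetFrame,roundingCompleteFrame,metaphaseEndFrame,ingressionEndFrame
#'   integer frame indices, non-decreasing in this order.
#' @slot frameIntervalMin positive frame interval in minutes (default 2,
#'   the overnight-imaging acquisition rate).
#' @export
setClass("DivisionEvents",
         representation(roundingOnsetFrame = "integer",
                        roundingCompleteFrame = "integer",
                        metaphaseEndFrame = "integer",
                        ingressionEndFrame = "integer",
                        frameIntervalMin = "numeric"))

setValidity("DivisionEvents", function(object) {
  f <- c(object@roundingOnsetFrame, object@roundingCompleteFrame,
         object@metaphaseEndFrame, object@ingressionEndFrame)
  msg <- character()
  if (is.unsorted(f))
    msg <- c(msg, paste0("event frames must satisfy rounding onset <= ",
                         "rounding complete <= metaphase end <= ingression end"))
  if (object@frameIntervalMin <= 0)
    msg <- c(msg, "frameIntervalMin must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DivisionEvents-class
#' @param roundingOnsetFrame,roundingCompleteFrame,metaphaseEndFrame,ingressionEndFrame
#'   integer frame indices.
#' @param frameIntervalMin frame interval in minutes.
#' @return A `DivisionEvents` object.
#' @export
DivisionEvents <- function(roundingOnsetFrame, roundingCompleteFrame,
                           metaphaseEndFrame, ingressionEndFrame,
                           frameIntervalMin = 2) {
  obj <- new("DivisionEvents",
             roundingOnsetFrame = as.integer(roundingOnsetFrame),
             roundingCompleteFrame = as.integer(roundingCompleteFrame),
             metaphaseEndFrame = as.integer(metaphaseEndFrame),
             ingressionEndFrame = as.integer(ingressionEndFrame),
             frameIntervalMin = as.numeric(frameIntervalMin))
  validObject(obj)
  obj
}
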