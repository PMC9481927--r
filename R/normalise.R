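# Total-count normalisation to a reference replicate and the
# reliability funnel that selects consistently detected proteins.

#' @describeIn SpectralCountSet-class per-replicate total raw spectral
#'   counts \eqn{T_j = \sum_i s_{ij}}, named by replicate column.
#'   Errors on an all-zero replicate.
#' @export
setMethod("replicateTotals", "SpectralCountSet", function(x) {
  tot <- colSums(spectralCounts(x))
  zero <- names(tot)[tot == 0]
  if (length(zero))
    degenerateError(sprintf("replicate(s) with zero total spectral count: %s",
                            paste(zero, collapse = ", ")))
  tot
})

#' @describeIn SpectralCountSet-class total-count normalisation: each
#'   raw count is divided by its replicate's total spectral count and
#'   multiplied by the reference replicate's total,
#'   \eqn{\tilde n_{ij} = s_{ij} T_{ref} / T_j}, so every replicate's
#'   normalised total equals the reference total, correcting run-to-run
#'   depth variation. The reference defaults to the first interphase
#'   replicate. Returns the object with a `"normalised"` assay and the
#'   totals recorded in `metadata()`. Re-normalising an
#'   already-normalised object against the same reference is the
#'   identity.
#' @param reference reference replicate column name.
#' @export
setMethod("normaliseToReference", "SpectralCountSet",
          function(x, reference = "interphase_1") {
  if (!is.character(reference) || length(reference) != 1L ||
      !(reference %in% colnames(x)))
    configError(sprintf("reference replicate '%s' not found among: %s",
                        paste(reference, collapse = ","),
                        paste(colnames(x), collapse = ", ")))
  tot <- replicateTotals(x)
  norm <- sweep(spectralCounts(x), 2L, tot[reference] / tot, `*`)
  SummarizedExperiment::assay(x, "normalised", withDimnames = FALSE) <- norm
  S4Vectors::metadata(x)$replicate_totals <- tot
  S4Vectors::metadata(x)$reference_replicate <- reference
  S4Vectors::metadata(x)$reference_total <- unname(tot[reference])
  x
})

#' @describeIn SpectralCountSet-class per-protein arithmetic mean of the
#'   chosen assay over each condition's replicates; returns a proteins x
#'   conditions matrix.
#' @param assay `"normalised"` (default) or `"counts"`.
#' @export
setMethod("conditionMeans", "SpectralCountSet",
          function(x, assay = "normalised") {
  m <- if (assay == "normalised") normalisedCounts(x)
       else if (assay == "counts") spectralCounts(x)
       else configError(sprintf("unknown assay '%s'", assay))
  cond <- replicateConditions(x)
  vapply(CONDITIONS, function(cn) {
    cols <- which(cond == cn)
    if (!length(cols)) degenerateError(sprintf("no replicates for '%s'", cn))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(x)))
})

#' @describeIn SpectralCountSet-class apply the reliability funnel: a
#'   protein is selected iff its unique peptide count meets
#'   `minUniquePeptides` and its mean normalised count meets
#'   `minMeanNormalised` in every condition (in at least one condition
#'   when `requireBothConditions` is `FALSE`). A positive mean threshold
#'   in both conditions enforces dual-condition presence, discarding
#'   e.g. nuclear proteins abundant in mitotic but absent from
#'   interphase fractions. Returns a list with `selected` (accessions,
#'   input order) and `funnel` (named counts: proteins detected — any
#'   raw count > 0 — per condition and overall, and the selected
#'   count).
#' @param criteria a [SelectionCriteria-class].
#' @export
setMethod("selectProteins", "SpectralCountSet",
          function(x, criteria = SelectionCriteria()) {
  stopifnot(is(criteria, "SelectionCriteria"))
  validObject(criteria)
  cm <- conditionMeans(x, assay = "normalised")
  up <- uniquePeptides(x)
  cmp <- if (criteria@strictInequality) `>` else `>=`
  okPep <- cmp(up, criteria@minUniquePeptides)
  okMean <- cmp(cm, criteria@minMeanNormalised)
  okCond <- if (criteria@requireBothConditions) apply(okMean, 1L, all)
            else apply(okMean, 1L, any)
  keep <- okPep & okCond

  raw <- spectralCounts(x)
  cond <- replicateConditions(x)
  detected <- vapply(CONDITIONS, function(cn)
    sum(rowSums(raw[, cond == cn, drop = FALSE]) > 0), numeric(1L))
  funnel <- c(detected_interphase = unname(detected["interphase"]),
              detected_mitosis = unname(detected["mitosis"]),
              detected_total = sum(rowSums(raw) > 0),
              selected = sum(keep))
  list(selected = rownames(x)[keep], funnel = funnel)
})
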