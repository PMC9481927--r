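# Per-protein differential testing on normalised spectral counts:
# pooled-variance Student t with a one-tailed p-value, volcano-table
# construction, BH adjustment, annotation against curated symbol sets
# and dual-evidence candidate ranking.

#' One-tailed two-sample Student t-test
#'
#' Classical pooled-variance (equal-variance) two-sample t statistic
#' with `n_a + n_b - 2` degrees of freedom and a one-tailed p-value.
#' The default `tail = "observed"` takes the tail in the direction of
#' the observed mean difference, `p = P(T >= |t|)`, so `p <= 0.5` and
#' identical groups give exactly `p = 0.5`. Note that under the null
#' this directed convention rejects at twice the nominal level (it is a
#' two-sided test at `2 * alpha` in disguise); use a fixed tail for
#' calibrated one-sided inference.
#'
#' Zero pooled variance is floored at `varFloor` so that degenerate rows
#' (constant replicates with different means) yield a finite, flagged
#' statistic instead of an infinity.
#'
#' @param a,b numeric vectors of replicate values, each of length >= 2.
#' @param tail `"observed"` (direction of the observed difference),
#'   `"greater"` (alternative: mean of `a` greater) or `"less"`.
#' @param varFloor variance floor for degenerate rows (default 1e-12).
#' @return A list with `t` (oriented `mean(a) - mean(b)`), `dof`, `p`
#'   and the logical `degenerate` flag.
#' @examples
#' oneTailedT(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.0107
#' @export
oneTailedT <- function(a, b, tail = c("observed", "greater", "less"),
                       varFloor = 1e-12) {
  tail <- match.arg(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    degenerateError("each group needs at least 2 replicates")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    formatError("group values must be finite")
  checkScalar(varFloor, "varFloor", lower = 0, inclusive = FALSE,
              upper = Inf)
  na <- length(a); nb <- length(b)
  dof <- na + nb - 2L
  diff <- mean(a) - mean(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dof
  degenerate <- FALSE
  if (sp2 < varFloor) {
    if (diff == 0)
      return(list(t = 0, dof = dof, p = 0.5, degenerate = FALSE))
    sp2 <- varFloor
    degenerate <- TRUE
  }
  t <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  p <- switch(tail,
              observed = pt(abs(t), dof, lower.tail = FALSE),
              greater = pt(t, dof, lower.tail = FALSE),
              less = pt(t, dof, lower.tail = TRUE))
  if (tail == "observed" && t == 0) p <- 0.5
  list(t = t, dof = dof, p = p, degenerate = degenerate)
}

#' Log2 enrichment between condition means
#'
#' `log2((meanMitosis + c) / (meanInterphase + c))`; positive values
#' indicate mitotic enrichment. A positive pseudocount `c` is required
#' when either mean is zero.
#'
#' @param meanInterphase,meanMitosis non-negative condition means.
#' @param pseudocount non-negative pseudocount (default 0).
#' @return The log2 enrichment.
#' @examples
#' log2Enrichment(2, 8)                    # 2
#' log2Enrichment(0, 8, pseudocount = 1)   # log2(9)
#' @export
log2Enrichment <- function(meanInterphase, meanMitosis, pseudocount = 0) {
  if (any(meanInterphase < 0) || any(meanMitosis < 0))
    formatError("condition means must be >= 0")
  checkScalar(pseudocount, "pseudocount", lower = 0)
  if (pseudocount == 0 && any(meanInterphase == 0 | meanMitosis == 0))
    degenerateError(
      "zero condition mean: a positive pseudocount is required")
  log2((meanMitosis + pseudocount) / (meanInterphase + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values via [stats::p.adjust()], after validating that
#' all p-values lie in (0, 1].
#'
#' @param p numeric p-values in (0, 1].
#' @return q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    formatError("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Build a volcano table of per-protein differential tests
#'
#' For each selected protein, tests its normalised counts between
#' conditions with [oneTailedT()] (t oriented mitosis minus interphase,
#' so positive t and positive enrichment both mean mitotic enrichment)
#' and assembles the volcano quantities: condition means, log2
#' enrichment, t, one-tailed p, \eqn{-\log_{10} p}, the significance
#' call at `alpha` and BH q-values. Rows follow the order of
#' `selected`. Degenerate-variance rows are flagged, never dropped;
#' with `pseudocount = 0`, rows with a zero condition mean get an `NA`
#' enrichment (with a warning) rather than aborting the table.
#'
#' @param x a normalised [SpectralCountSet-class].
#' @param selected accessions to test (default: all proteins).
#' @param alpha significance level on the one-tailed p (default 0.05,
#'   the \eqn{-\log_{10} p = 1.3} volcano cut-off).
#' @param pseudocount pseudocount for [log2Enrichment()] (default 0).
#' @param tail tail mode passed to [oneTailedT()] (default
#'   `"observed"`; with `"greater"` the alternative is mitotic
#'   enrichment).
#' @param varFloor variance floor for degenerate rows.
#' @return A [DifferentialResults-class], one row per selected protein.
#' @export
volcanoTable <- function(x, selected = NULL, alpha = 0.05,
                         pseudocount = 0,
                         tail = c("observed", "greater", "less"),
                         varFloor = 1e-12) {
  tail <- match.arg(tail)
  stopifnot(is(x, "SpectralCountSet"))
  checkScalar(alpha, "alpha", lower = 0, upper = 1, inclusive = FALSE)
  if (is.null(selected)) selected <- rownames(x)
  missing <- setdiff(selected, rownames(x))
  if (length(missing))
    formatError(sprintf("selected accession(s) not in table: %s",
                        paste(utils::head(missing, 5L), collapse = ", ")))
  norm <- normalisedCounts(x)[selected, , drop = FALSE]
  cond <- replicateConditions(x)
  icols <- which(cond == "interphase")
  mcols <- which(cond == "mitosis")
  tests <- lapply(seq_along(selected), function(i) {
    # orient a = mitosis so t > 0 means mitotic enrichment; the
    # "greater" tail is then the mitosis-enriched alternative
    oneTailedT(norm[i, mcols], norm[i, icols], tail = tail,
               varFloor = varFloor)
  })
  mi <- rowMeans(norm[, icols, drop = FALSE])
  mm <- rowMeans(norm[, mcols, drop = FALSE])
  zero <- (mi == 0 | mm == 0)
  enr <- rep(NA_real_, length(selected))
  if (pseudocount == 0) {
    if (any(zero))
      warning(sprintf(
        "%d protein(s) with a zero condition mean: log2 enrichment set to NA",
        sum(zero)), call. = FALSE)
    enr[!zero] <- log2Enrichment(mi[!zero], mm[!zero])
  } else {
    enr <- log2Enrichment(mi, mm, pseudocount)
  }
  p <- vapply(tests, `[[`, 0, "p")
  res <- S4Vectors::DataFrame(
    accession = selected,
    gene_symbol = unname(geneSymbols(x)[selected]),
    mean_interphase = unname(mi),
    mean_mitosis = unname(mm),
    log2_enrichment = unname(enr),
    t_statistic = vapply(tests, `[[`, 0, "t"),
    dof = vapply(tests, function(z) as.integer(z$dof), 1L),
    p_one_tailed = p,
    neg_log10_p = -log10(p),
    significant = p < alpha,
    q_bh = bhAdjust(p),
    degenerate_variance = vapply(tests, `[[`, TRUE, "degenerate"),
    row.names = selected)
  new("DifferentialResults", res,
      metadata = list(alpha = alpha, tail = tail, pseudocount = pseudocount))
}

.reportSummary <- function(df) {
  c(n = nrow(df),
    significant = sum(df$significant),
    actin_related = sum(df$actin_related),
    significant_actin_related = sum(df$actin_related & df$significant),
    screen_tested = sum(df$screen_tested),
    screen_hit = sum(df$screen_hit),
    dual_evidence = sum(df$dual_evidence))
}

#' Annotate differential results with curated symbol sets
#'
#' Flags each protein by exact gene-symbol membership in the curated
#' actin-related set and the mechanical-screen tested/hit sets, and
#' derives the dual-evidence flag (significant differential change AND
#' screen hit). Identifiers in the sets that match no result are
#' counted and reported via a message, never an error.
#'
#' @param results a [DifferentialResults-class].
#' @param sets an [AnnotationSets-class].
#' @param caseInsensitive match symbols case-insensitively
#'   (default `FALSE`).
#' @return A [CandidateReport-class]; `metadata()$summary` holds the
#'   subset counts and `metadata()$unmatched` the per-set counts of
#'   unmatched identifiers.
#' @export
annotateResults <- function(results, sets, caseInsensitive = FALSE) {
  stopifnot(is(results, "DifferentialResults"), is(sets, "AnnotationSets"))
  validObject(sets)
  key <- function(v) if (caseInsensitive) toupper(v) else v
  sym <- key(results$gene_symbol)
  flag <- function(set) sym %in% key(set)
  out <- S4Vectors::DataFrame(results)
  out$actin_related <- flag(sets@actinRelated)
  out$screen_tested <- flag(sets@screenTested)
  out$screen_hit <- flag(sets@screenHit)
  out$dual_evidence <- out$significant & out$screen_hit
  unmatched <- vapply(
    list(actin_related = sets@actinRelated,
         screen_tested = sets@screenTested,
         screen_hit = sets@screenHit),
    function(set) sum(!(key(set) %in% sym)), numeric(1L))
  if (sum(unmatched) > 0)
    message(sprintf("annotateResults: %d annotation identifier(s) matched no result",
                    sum(unmatched)))
  new("CandidateReport", out,
      metadata = c(S4Vectors::metadata(results),
                   list(summary = .reportSummary(out),
                        unmatched = unmatched)))
}

#' Rank dual-evidence candidates
#'
#' Returns the proteins supported by both evidence streams — a
#' significant change in cortical levels and a hit in the mechanical
#' screen — ordered by ascending one-tailed p-value.
#'
#' @param report a [CandidateReport-class].
#' @return A `DataFrame` subset of the report, best candidate first.
#' @export
rankDualEvidence <- function(report) {
  stopifnot(is(report, "CandidateReport"))
  hits <- report[report$dual_evidence, , drop = FALSE]
  hits[order(hits$p_one_tailed), , drop = FALSE]
}
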