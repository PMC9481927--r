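# Tabular IO: spectral-count tables (Scaffold-style exports converted
# to TSV), plain-text gene lists, differential-result tables, contour
# CSVs and qPCR CT tables. Parsing is strict: malformed cells raise
# format errors instead of silently becoming NA.

.INT_RE <- "^[0-9]+$"

.readDelim <- function(path, sep) {
  if (!file.exists(path)) formatError(sprintf("file not found: %s", path))
  read.delim(path, sep = sep, header = TRUE, colClasses = "character",
             check.names = FALSE, strip.white = TRUE,
             comment.char = "", quote = "")
}

.sepFor <- function(dialect) {
  dialect <- match.arg(dialect, c("tab", "comma"))
  if (dialect == "tab") "\t" else ","
}

#' Read a spectral-count table
#'
#' Reads a protein-level count table in the canonical dialect: a header
#' row with columns `accession`, `gene_symbol`, `unique_peptides`, then
#' one raw-count column per replicate named `<condition>_<index>`
#' (e.g. `interphase_1`, `mitosis_3`). This is the shape of a
#' protein-report export from spectral-counting software once converted
#' to TSV.
#'
#' @param path file path.
#' @param dialect `"tab"` (canonical) or `"comma"`.
#' @return A [SpectralCountSet-class]; row order preserved.
#' @export
readCountTable <- function(path, dialect = "tab") {
  df <- .readDelim(path, .sepFor(dialect))
  fixed <- c("accession", "gene_symbol", "unique_peptides")
  missing <- setdiff(fixed, colnames(df))
  if (length(missing))
    formatError(sprintf("count table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  repCols <- setdiff(colnames(df), fixed)
  m <- regmatches(repCols, regexec("^([A-Za-z]+)_([0-9]+)$", repCols))
  bad <- repCols[lengths(m) != 3L]
  if (length(bad))
    formatError(sprintf(
      "replicate columns must be named <condition>_<index>; offending: %s",
      paste(bad, collapse = ", ")))
  condition <- vapply(m, `[`, "", 2L)
  repIndex <- as.integer(vapply(m, `[`, "", 3L))
  if (!all(condition %in% CONDITIONS))
    formatError(sprintf("unknown condition(s): %s",
                        paste(setdiff(condition, CONDITIONS), collapse = ", ")))
  if (!all(CONDITIONS %in% condition))
    formatError(sprintf("missing condition: %s",
                        paste(setdiff(CONDITIONS, condition), collapse = ", ")))
  if (anyDuplicated(df$accession)) {
    dup <- unique(df$accession[duplicated(df$accession)])
    formatError(sprintf("duplicate accession(s): %s",
                        paste(dup, collapse = ", ")))
  }
  .intCol <- function(vals, colName) {
    badRow <- which(!grepl(.INT_RE, vals))
    if (length(badRow))
      formatError(sprintf(
        "non-integer value '%s' in column '%s', row %d",
        vals[badRow[1L]], colName, badRow[1L]))
    as.integer(vals)
  }
  up <- .intCol(df$unique_peptides, "unique_peptides")
  counts <- vapply(repCols, function(cn) .intCol(df[[cn]], cn),
                   integer(nrow(df)))
  counts <- matrix(counts, nrow = nrow(df),
                   dimnames = list(df$accession, repCols))
  SpectralCountSet(counts, condition = condition, replicate = repIndex,
                   geneSymbol = df$gene_symbol, uniquePeptides = up)
}

#' Write a spectral-count table
#'
#' Writes the raw counts of a [SpectralCountSet-class] in the canonical
#' TSV dialect; [readCountTable()] recovers the table losslessly.
#'
#' @param x a `SpectralCountSet`.
#' @param path output file path.
#' @param dialect `"tab"` or `"comma"`.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path, dialect = "tab") {
  stopifnot(is(x, "SpectralCountSet"))
  df <- data.frame(accession = rownames(x),
                   gene_symbol = unname(geneSymbols(x)),
                   unique_peptides = unname(uniquePeptides(x)),
                   spectralCounts(x),
                   check.names = FALSE)
  .writeTable(df, path, .sepFor(dialect))
}

.writeTable <- function(df, path, sep = "\t") {
  ok <- tryCatch({
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    cortexStop(sprintf("cannot write '%s': %s", path,
                       conditionMessage(ok)), "cortex_io_error")
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; `#` starts a comment (full-line or
#' trailing); whitespace is trimmed; duplicates are dropped; case is
#' preserved. An empty result raises a warning.
#'
#' @param path file path.
#' @return Character vector of unique identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) formatError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- unique(lines[nzchar(lines)])
  if (!length(ids))
    warning(sprintf("gene list '%s' is empty", path), call. = FALSE)
  ids
}

#' Write a plain-text gene list
#'
#' @param ids character identifiers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(ids, path) {
  writeLines(unique(as.character(ids)), path)
  invisible(path)
}

.RESULT_COLS <- c("accession", "gene_symbol", "mean_interphase",
                  "mean_mitosis", "log2_enrichment", "t_statistic", "dof",
                  "p_one_tailed", "neg_log10_p", "significant", "q_bh",
                  "degenerate_variance")
.ANNOT_COLS <- c("actin_related", "screen_tested", "screen_hit",
                 "dual_evidence")

#' Write a differential-results table
#'
#' Emits a TSV with the stable column order: accession, gene symbol,
#' per-condition means, log2 enrichment, t, degrees of freedom,
#' one-tailed p, -log10 p, significance and degeneracy flags and BH
#' q-value — plus the annotation flags when given a
#' [CandidateReport-class].
#'
#' @param res a [DifferentialResults-class] or [CandidateReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(res, path) {
  stopifnot(is(res, "DifferentialResults"))
  cols <- .RESULT_COLS
  if (is(res, "CandidateReport")) cols <- c(cols, .ANNOT_COLS)
  .writeTable(as.data.frame(res)[, cols], path)
}

#' Read back a differential-results table
#'
#' Inverse of [writeResultsTable()]; used to chain pipeline stages run
#' as separate commands.
#'
#' @param path file path.
#' @return A [DifferentialResults-class] (or [CandidateReport-class]
#'   when annotation flags are present).
#' @export
readResultsTable <- function(path) {
  df <- .readDelim(path, "\t")
  missing <- setdiff(.RESULT_COLS, colnames(df))
  if (length(missing))
    formatError(sprintf("results table missing column(s): %s",
                        paste(missing, collapse = ", ")))
  num <- c("mean_interphase", "mean_mitosis", "log2_enrichment",
           "t_statistic", "p_one_tailed", "neg_log10_p", "q_bh")
  out <- S4Vectors::DataFrame(row.names = df$accession)
  out$accession <- df$accession
  out$gene_symbol <- df$gene_symbol
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- is.na(v) & !is.na(df[[cn]]) & !(df[[cn]] %in% c("NA", "NaN", ""))
    if (any(bad))
      formatError(sprintf("non-numeric value in column '%s'", cn))
    out[[cn]] <- v
  }
  out$dof <- as.integer(df$dof)
  out$significant <- as.logical(df$significant)
  out$degenerate_variance <- as.logical(df$degenerate_variance)
  if (all(.ANNOT_COLS %in% colnames(df))) {
    for (cn in .ANNOT_COLS) out[[cn]] <- as.logical(df[[cn]])
    new("CandidateReport", out[, c(.RESULT_COLS, .ANNOT_COLS)],
        metadata = list(summary = .reportSummary(out)))
  } else {
    new("DifferentialResults", out[, .RESULT_COLS])
  }
}

#' Read cell contours from CSV
#'
#' Expects columns `frame`, `vertex_index`, `x_um`, `y_um`; one polygon
#' per frame, vertices ordered by `vertex_index`.
#'
#' @param path file path.
#' @return A named list of [CellContour-class], one per frame.
#' @export
readContours <- function(path) {
  df <- .readDelim(path, ",")
  need <- c("frame", "vertex_index", "x_um", "y_um")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    formatError(sprintf("contour CSV missing column(s): %s",
                        paste(missing, collapse = ", ")))
  xy <- lapply(df[c("x_um", "y_um")], function(v) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) formatError("non-numeric coordinate in contour CSV")
    out
  })
  frame <- as.integer(df$frame)
  idx <- as.integer(df$vertex_index)
  out <- lapply(split(seq_len(nrow(df)), frame), function(i) {
    i <- i[order(idx[i])]
    CellContour(cbind(xy$x_um[i], xy$y_um[i]), frameIndex = frame[i[1L]])
  })
  out
}

#' Write cell contours to CSV
#'
#' @param contours a [CellContour-class] or list thereof.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeContours <- function(contours, path) {
  if (is(contours, "CellContour")) contours <- list(contours)
  rows <- lapply(contours, function(ct) {
    v <- vertices(ct)
    data.frame(frame = ct@frameIndex, vertex_index = seq_len(nrow(v)),
               x_um = v[, 1L], y_um = v[, 2L])
  })
  .writeTable(do.call(rbind, rows), path, sep = ",")
}

#' Read a qPCR CT table
#'
#' Expects CSV columns `sample`, `gene`, `ct` with finite positive CT
#' cycle values.
#'
#' @param path file path.
#' @return A data.frame with character `sample`/`gene` and numeric `ct`.
#' @export
readCtTable <- function(path) {
  df <- .readDelim(path, ",")
  missing <- setdiff(c("sample", "gene", "ct"), colnames(df))
  if (length(missing))
    formatError(sprintf("CT table missing column(s): %s",
                        paste(missing, collapse = ", ")))
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct) | !is.finite(ct) | ct <= 0)
  if (length(bad))
    formatError(sprintf("invalid CT value '%s' in row %d",
                        df$ct[bad[1L]], bad[1L]))
  data.frame(sample = df$sample, gene = df$gene, ct = ct)
}
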