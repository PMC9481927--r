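# Independent oracles and small fixture builders used across the suite.

# Pooled-variance t statistic, written independently of the package
# implementation (plain formula transcription).
oracleT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Monte-Carlo estimate of P(T >= |t_obs|) under the fitted normal null
# (pooled variance, common mean), i.e. a simulation of the Student tail
# probability the one-tailed test reports. Returns the estimate and its
# binomial standard error.
mcNullTailOracle <- function(a, b, draws = 1e5, seed = 99) {
  tObs <- abs(oracleT(a, b))
  na <- length(a); nb <- length(b)
  sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2))
  set.seed(seed)
  aStar <- matrix(rnorm(draws * na, 0, sp), draws)
  bStar <- matrix(rnorm(draws * nb, 0, sp), draws)
  tStar <- (rowMeans(aStar) - rowMeans(bStar)) /
    sqrt(((rowSums((aStar - rowMeans(aStar))^2) +
           rowSums((bStar - rowMeans(bStar))^2)) / (na + nb - 2)) *
         (1 / na + 1 / nb))
  pHat <- mean(tStar >= tObs)
  list(p = pHat, se = sqrt(pHat * (1 - pHat) / draws))
}

# Exact permutation upper-tail probability over all distinct
# relabellings (20 for a 3-vs-3 design): P_perm(t >= |t_obs|).
exactPermutationP <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  tObs <- abs(oracleT(a, b))
  tPerm <- apply(idx, 2L, function(i) oracleT(pool[i], pool[-i]))
  mean(tPerm >= tObs - 1e-12)
}

# Small count table with exact per-condition normalised means. Depth is
# balanced (equal column totals) via a ballast row so that normalised
# counts equal raw counts and the means are the ones handed in.
makeMeanControlledScs <- function(interphaseRows, mitosisRows,
                                  uniquePeptides,
                                  geneSymbol = NULL) {
  counts <- cbind(interphaseRows, mitosisRows)
  tot <- colSums(counts)
  ballast <- max(tot) - tot + 5L
  counts <- rbind(counts, ballast)
  n <- nrow(counts)
  rownames(counts) <- c(sprintf("P%03d", seq_len(n - 1L)), "BALLAST")
  if (is.null(geneSymbol))
    geneSymbol <- c(sprintf("G%03d", seq_len(n - 1L)), "BAL")
  else geneSymbol <- c(geneSymbol, "BAL")
  SpectralCountSet(counts,
                   condition = rep(c("interphase", "mitosis"),
                                   c(ncol(interphaseRows),
                                     ncol(mitosisRows))),
                   geneSymbol = geneSymbol,
                   uniquePeptides = c(uniquePeptides, 99L))
}

# Regular n-gon contour of circumradius r.
regularPolygon <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  CellContour(cbind(r * cos(th), r * sin(th)))
}

# Analytic ellipse perimeter via the complete elliptic integral E.
ellipsePerimeter <- function(a, b) {
  m <- 1 - (b / a)^2
  4 * a * pracma::ellipke(m)$e
}
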