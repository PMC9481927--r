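# One-tailed Student t machinery, volcano construction, annotation and
# dual-evidence ranking.

test_that("the pooled t-test reproduces closed-form and reference values", {
  # identical groups: t = 0, p exactly 0.5
  same <- oneTailedT(c(3, 3, 3), c(3, 3, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 0.5)
  expect_false(same$degenerate)

  res <- oneTailedT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.6742346, tolerance = 1e-6)
  expect_identical(res$dof, 4L)
  expect_equal(res$p, 0.0107, tolerance = 1e-2)
  # independent route: stats::t.test equal-variance, halved two-sided p
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p, tt$p.value / 2, tolerance = 1e-12)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)

  expect_error(oneTailedT(c(1), c(2, 3)), class = "cortex_degenerate_error")
})

test_that("label swap flips t but leaves the observed-direction p alone", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(3, 10, 2); b <- rnorm(3, 12, 2)
    r1 <- oneTailedT(a, b)
    r2 <- oneTailedT(b, a)
    expect_equal(r1$t, -r2$t)
    expect_equal(r1$p, r2$p)
    # fixed tails are complementary
    expect_equal(oneTailedT(a, b, tail = "greater")$p +
                 oneTailedT(a, b, tail = "less")$p, 1)
    # scale invariance
    r3 <- oneTailedT(5 * a, 5 * b)
    expect_equal(r3$t, r1$t, tolerance = 1e-12)
    expect_equal(r3$p, r1$p, tolerance = 1e-12)
  }
})

test_that("zero-variance groups with different means are floored and flagged", {
  res <- oneTailedT(c(1, 1, 1), c(2, 2, 2))
  expect_true(res$degenerate)
  expect_true(is.finite(res$t))
  expect_lt(res$p, 1e-6)
  # a larger floor gives a milder statistic
  res2 <- oneTailedT(c(1, 1, 1), c(2, 2, 2), varFloor = 1)
  expect_false(abs(res2$t) > abs(res$t))
})

test_that("t p-values agree with simulation and permutation oracles", {
  fixtures <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(10, 12, 11), b = c(10.5, 11.5, 12)),
    list(a = c(5, 9, 7), b = c(6, 6.5, 8)))
  for (fx in fixtures) {
    p <- oneTailedT(fx$a, fx$b)$p
    mc <- mcNullTailOracle(fx$a, fx$b, draws = 2e4)
    expect_lt(abs(p - mc$p), 3 * max(mc$se, 1e-4))
    # exact 20-relabelling permutation p agrees only coarsely: its
    # resolution is 1/20 and its null has discrete atoms
    expect_lt(abs(p - exactPermutationP(fx$a, fx$b)), 0.1)
  }
})

test_that("log2 enrichment follows its closed form", {
  expect_identical(log2Enrichment(4, 4), 0)
  expect_identical(log2Enrichment(2, 8), 2)
  expect_equal(log2Enrichment(0, 8, pseudocount = 1), log2(9))
  expect_error(log2Enrichment(0, 8), class = "cortex_degenerate_error")
  expect_error(log2Enrichment(-1, 8), class = "cortex_format_error")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, 0)), class = "cortex_format_error")
  expect_error(bhAdjust(c(0.5, 1.2)), class = "cortex_format_error")
  # q >= p and q non-decreasing in p-rank
  set.seed(1)
  p <- runif(200)
  q <- bhAdjust(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("volcano tables are row-aligned, flagged and internally consistent", {
  sim <- simulateCounts(SimulationConfig(nProteins = 200, seed = 17))
  norm <- normaliseToReference(sim$counts)
  sel <- selectProteins(norm)$selected
  res <- volcanoTable(norm, sel)
  expect_identical(res$accession, sel)
  expect_equal(res$neg_log10_p, -log10(res$p_one_tailed))
  expect_identical(res$significant, res$p_one_tailed < 0.05)
  expect_true(all(res$p_one_tailed <= 0.5))  # observed-direction tail
  # enrichment sign matches the direction of the mean difference
  pos <- !is.na(res$log2_enrichment) & res$mean_mitosis != res$mean_interphase
  expect_identical(sign(res$log2_enrichment[pos]),
                   sign(res$mean_mitosis[pos] - res$mean_interphase[pos]))
  expect_identical(sign(res$t_statistic[pos]),
                   sign(res$log2_enrichment[pos]))
  expect_error(volcanoTable(norm, c(sel[1], "NOPE")),
               class = "cortex_format_error")

  # constant identical triplicates: p = 0.5, never significant
  scs <- makeMeanControlledScs(rbind(c(3L, 3L, 3L)), rbind(c(3L, 3L, 3L)),
                               uniquePeptides = 5L)
  one <- volcanoTable(normaliseToReference(scs), "P001")
  expect_identical(one$p_one_tailed, 0.5)
  expect_false(one$significant)
})

test_that("annotation flags by exact symbol membership and counts subsets", {
  sim <- simulateCounts(SimulationConfig(nProteins = 100, seed = 19))
  norm <- normaliseToReference(sim$counts)
  res <- suppressWarnings(volcanoTable(norm))

  empty <- annotateResults(res, AnnotationSets())
  s <- S4Vectors::metadata(empty)$summary
  expect_equal(unname(s[c("actin_related", "screen_tested", "screen_hit",
                          "dual_evidence")]), c(0, 0, 0, 0))

  all <- annotateResults(res, AnnotationSets(actinRelated = res$gene_symbol))
  expect_equal(unname(S4Vectors::metadata(all)$summary["actin_related"]),
               nrow(res))

  # unmatched identifiers are reported, never an error
  expect_message(
    annotateResults(res, AnnotationSets(actinRelated = c("NOT_A_GENE"))),
    "matched no result")
  # matching is case-sensitive unless asked otherwise
  lower <- annotateResults(res, AnnotationSets(
    actinRelated = tolower(res$gene_symbol[1])))
  expect_equal(sum(lower$actin_related), 0)
  lowerCI <- annotateResults(res, AnnotationSets(
    actinRelated = tolower(res$gene_symbol[1])), caseInsensitive = TRUE)
  expect_equal(sum(lowerCI$actin_related), 1)

  expect_error(AnnotationSets(screenHit = "MYH9"), "MYH9")
})

test_that("dual-evidence ranking returns significant screen hits by ascending p", {
  # two clearly changed proteins among the screen hits, one flat
  scs <- makeMeanControlledScs(
    interphaseRows = rbind(c(30L, 28L, 32L), c(10L, 11L, 9L),
                           c(20L, 21L, 19L), c(50L, 48L, 52L)),
    mitosisRows = rbind(c(60L, 63L, 58L), c(22L, 24L, 20L),
                        c(20L, 19L, 21L), c(51L, 49L, 50L)),
    uniquePeptides = c(20L, 8L, 10L, 30L),
    geneSymbol = c("MYH9", "SEPT9", "FLAT1", "FLAT2"))
  res <- volcanoTable(normaliseToReference(scs))
  sets <- AnnotationSets(
    actinRelated = c("MYH9", "SEPT9", "FLAT1", "FLAT2"),
    screenTested = c("MYH9", "SEPT9", "FLAT1", "FLAT2"),
    screenHit = c("MYH9", "SEPT9", "FLAT2"))
  report <- annotateResults(res, sets)
  ranked <- rankDualEvidence(report)
  expect_setequal(ranked$gene_symbol, c("MYH9", "SEPT9"))
  expect_true(all(diff(ranked$p_one_tailed) >= 0))

  none <- annotateResults(res, AnnotationSets())
  expect_equal(nrow(rankDualEvidence(none)), 0)
})

test_that("the observed-direction tail rejects at twice the nominal level under the null", {
  # choosing the tail after seeing the data is a two-sided test at
  # 2*alpha: the null rejection rate must sit near 0.10, not 0.05
  sim <- simulateCounts(SimulationConfig(nProteins = 2000, fractionDa = 0,
                                         fractionConditionSpecific = 0,
                                         seed = 616))
  res <- suppressWarnings(volcanoTable(normaliseToReference(sim$counts),
                                       tail = "observed"))
  frac <- mean(res$significant)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.125)
})
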