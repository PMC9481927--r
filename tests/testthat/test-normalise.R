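# Reference-replicate normalisation and the selection funnel.

test_that("replicate totals are column sums and zero totals are rejected", {
  m <- matrix(c(1L, 3L, 2L, 4L), 2, 2,
              dimnames = list(c("P1", "P2"), NULL))
  scs <- SpectralCountSet(m, condition = c("interphase", "mitosis"),
                          geneSymbol = c("A", "B"),
                          uniquePeptides = c(2L, 2L))
  expect_equal(unname(replicateTotals(scs)), c(4, 6))

  sim <- simulateCounts(SimulationConfig(nProteins = 100, seed = 4))
  expect_equal(replicateTotals(sim$counts),
               apply(spectralCounts(sim$counts), 2, sum))

  m0 <- m; m0[, 2] <- 0L
  scs0 <- SpectralCountSet(m0, condition = c("interphase", "mitosis"),
                           geneSymbol = c("A", "B"),
                           uniquePeptides = c(2L, 2L))
  expect_error(replicateTotals(scs0), "mitosis_1",
               class = "cortex_degenerate_error")
})

test_that("normalisation rescales by the reference total", {
  # totals 100 and 50 with the first (interphase) replicate as
  # reference: a count of 5 in the second replicate doubles to 10
  m <- matrix(c(95L, 5L, 45L, 5L), 2, 2,
              dimnames = list(c("P1", "P2"), NULL))
  scs <- SpectralCountSet(m, condition = c("interphase", "mitosis"),
                          geneSymbol = c("A", "B"),
                          uniquePeptides = c(2L, 2L))
  norm <- normaliseToReference(scs)
  expect_equal(normalisedCounts(norm)["P2", "mitosis_1"], 10)
  # the reference column is unchanged
  expect_equal(normalisedCounts(norm)[, "interphase_1"],
               spectralCounts(scs)[, "interphase_1"] + 0)
  expect_identical(referenceReplicate(norm), "interphase_1")
  expect_error(normaliseToReference(scs, "mitosis_9"),
               class = "cortex_config_error")
})

test_that("equal replicate totals make normalisation the identity", {
  sim <- simulateCounts(SimulationConfig(nProteins = 60, seed = 10))
  raw <- spectralCounts(sim$counts)
  tot <- colSums(raw)
  raw[1, ] <- raw[1, ] + as.integer(max(tot) - tot)  # balance columns
  scs <- SpectralCountSet(raw, condition = replicateConditions(sim$counts),
                          geneSymbol = geneSymbols(sim$counts),
                          uniquePeptides = uniquePeptides(sim$counts))
  expect_equal(normalisedCounts(normaliseToReference(scs)), raw + 0)
})

test_that("normalised column totals all equal the reference total", {
  for (seed in c(1, 2, 3)) {
    sim <- simulateCounts(SimulationConfig(nProteins = 150, seed = seed))
    norm <- normaliseToReference(sim$counts)
    tot <- colSums(normalisedCounts(norm))
    ref <- S4Vectors::metadata(norm)$reference_total
    expect_true(all(abs(tot - ref) <= 1e-9 * ref))
    # independent summation oracle for the reference total
    expect_equal(ref, sum(spectralCounts(sim$counts)[, "interphase_1"]))
  }
})

test_that("normalising an already-normalised table is idempotent", {
  sim <- simulateCounts(SimulationConfig(nProteins = 80, seed = 12))
  n1 <- normaliseToReference(sim$counts)
  # re-running on the same object and reference must not change the
  # normalised assay: the transform is a fixed rescaling of raw counts
  n2 <- normaliseToReference(n1)
  expect_identical(normalisedCounts(n1), normalisedCounts(n2))
})

test_that("condition means average the normalised counts", {
  scs <- makeMeanControlledScs(
    interphaseRows = rbind(c(2L, 2L, 2L), c(0L, 0L, 6L)),
    mitosisRows = rbind(c(4L, 4L, 4L), c(3L, 3L, 3L)),
    uniquePeptides = c(5L, 5L))
  cm <- conditionMeans(normaliseToReference(scs))
  expect_equal(cm["P001", "interphase"], 2)
  expect_equal(cm["P002", "interphase"], 2)
  expect_equal(cm["P001", "mitosis"], 4)

  sim <- simulateCounts(SimulationConfig(nProteins = 50, seed = 14))
  norm <- normaliseToReference(sim$counts)
  cm <- conditionMeans(norm)
  nc <- normalisedCounts(norm)
  cond <- replicateConditions(norm)
  expect_equal(cm[, "mitosis"],
               rowMeans(nc[, cond == "mitosis"]))  # brute-force oracle
})

test_that("the selection funnel applies both criteria inclusively", {
  scs <- makeMeanControlledScs(
    interphaseRows = rbind(c(10L, 10L, 10L),  # u = 1: peptide fail
                           c(3L, 2L, 4L),     # absent in mitosis
                           c(2L, 2L, 2L),     # boundary: included
                           c(1L, 1L, 1L)),    # below mean threshold
    mitosisRows = rbind(c(10L, 10L, 10L),
                        c(0L, 0L, 0L),
                        c(2L, 2L, 2L),
                        c(9L, 9L, 9L)),
    uniquePeptides = c(1L, 5L, 2L, 8L))
  sel <- selectProteins(normaliseToReference(scs))
  expect_identical(sel$selected, c("P003", "BALLAST"))
  expect_equal(unname(sel$funnel["selected"]), 2)
  expect_equal(unname(sel$funnel["detected_interphase"]), 5)
  expect_equal(unname(sel$funnel["detected_mitosis"]), 4)

  # the strict reading excludes the boundary protein
  strict <- selectProteins(normaliseToReference(scs),
                           SelectionCriteria(strictInequality = TRUE))
  expect_false("P003" %in% strict$selected)
})

test_that("raising thresholds never enlarges the selected set", {
  sim <- simulateCounts(SimulationConfig(nProteins = 300, seed = 21))
  norm <- normaliseToReference(sim$counts)
  prev <- NULL
  for (minMean in c(0.5, 1, 2, 4, 8)) {
    cur <- selectProteins(norm, SelectionCriteria(
      minMeanNormalised = minMean))$selected
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  loose <- selectProteins(norm, SelectionCriteria(1, 1))$selected
  tight <- selectProteins(norm, SelectionCriteria(3, 3))$selected
  expect_true(all(tight %in% loose))
})

test_that("permuting protein rows permutes the selection identically", {
  sim <- simulateCounts(SimulationConfig(nProteins = 120, seed = 33))
  norm <- normaliseToReference(sim$counts)
  sel <- selectProteins(norm)
  perm <- sample(nrow(norm))
  selPerm <- selectProteins(normaliseToReference(sim$counts[perm, ]))
  expect_setequal(selPerm$selected, sel$selected)
  expect_identical(selPerm$funnel, sel$funnel)
  expect_identical(selPerm$selected,
                   rownames(norm)[perm][rownames(norm)[perm] %in%
                                        sel$selected])
})
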