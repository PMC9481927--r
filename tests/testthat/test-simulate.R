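# Synthetic-data generator: determinism, planted truth, count law.

test_that("identical config and seed give bit-identical output", {
  cfg <- SimulationConfig(nProteins = 200, seed = 123)
  s1 <- simulateCounts(cfg)
  s2 <- simulateCounts(cfg)
  expect_identical(spectralCounts(s1$counts), spectralCounts(s2$counts))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  expect_identical(uniquePeptides(s1$counts), uniquePeptides(s2$counts))
  # a different seed must change the data
  s3 <- simulateCounts(SimulationConfig(nProteins = 200, seed = 124))
  expect_false(identical(spectralCounts(s1$counts),
                         spectralCounts(s3$counts)))
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- rnorm(3)
  set.seed(42)
  invisible(simulateCounts(SimulationConfig(nProteins = 20, seed = 9)))
  expect_identical(rnorm(3), before)
})

test_that("fractionDa = 0 plants no effects", {
  sim <- simulateCounts(SimulationConfig(nProteins = 300, fractionDa = 0,
                                         seed = 5))
  expect_false(any(sim$truth$is_da))
  expect_identical(sim$truth$true_log2_effect, rep(0, 300))
})

test_that("truth labels are coherent with the generated counts", {
  sim <- simulateCounts(SimulationConfig(nProteins = 800, seed = 31))
  tr <- sim$truth
  cts <- spectralCounts(sim$counts)
  cond <- replicateConditions(sim$counts)
  # non-DA implies zero effect; labels align one-to-one with rows
  expect_true(all(tr$true_log2_effect[!tr$is_da] == 0))
  expect_identical(rownames(tr), rownames(cts))
  # condition-specific proteins are structural zeros in interphase
  cs <- tr$is_condition_specific
  expect_true(any(cs))
  expect_true(all(cts[cs, cond == "interphase"] == 0))
  expect_true(any(rowSums(cts[cs, cond == "mitosis", drop = FALSE]) > 0))
  # DA and condition-specific are disjoint
  expect_false(any(tr$is_da & cs))
})

test_that("equal depth factors give replicate totals within 3 SE", {
  phi <- 0.01
  cfg <- SimulationConfig(nProteins = 2000, dispersion = phi,
                          depthFactors = rep(1, 6), fractionDa = 0,
                          fractionConditionSpecific = 0, seed = 77)
  sim <- simulateCounts(cfg)
  mu <- sim$truth$baseline_mean
  # total over proteins: Var(T_j) = sum_i (mu_i + phi mu_i^2)
  seTotal <- sqrt(sum(mu + phi * mu^2))
  tot <- colSums(spectralCounts(sim$counts))
  expect_true(all(abs(tot - sum(mu)) < 3 * seTotal))
})

test_that("realised log2 ratios of DA proteins track the planted mean", {
  cfg <- SimulationConfig(nProteins = 3000, dispersion = 1e-3,
                          baselineLogMean = log(500), baselineLogSd = 0.3,
                          depthFactors = rep(1, 6), fractionDa = 0.3,
                          effectLog2Mean = 2, effectLog2Sd = 0,
                          fractionConditionSpecific = 0, seed = 8)
  sim <- simulateCounts(cfg)
  # raw counts with equal depth: the per-protein ratio is 2^delta
  cm <- conditionMeans(sim$counts, assay = "counts")
  da <- sim$truth$is_da
  ratio <- log2(cm[da, "mitosis"] / cm[da, "interphase"])
  expect_lt(abs(mean(ratio) - 2), 0.05)
})

test_that("unique peptide counts are positive and grow with abundance", {
  sim <- simulateCounts(SimulationConfig(nProteins = 1000, seed = 3))
  up <- uniquePeptides(sim$counts)
  expect_true(all(up >= 1))
  expect_true(all(up == round(up)))
  expect_gt(cor(up, log10(sim$truth$baseline_mean + 1)), 0.5)
})

test_that("invalid simulation settings raise configuration errors naming the field", {
  expect_error(SimulationConfig(fractionDa = 1.2), "fractionDa",
               class = "cortex_config_error")
  expect_error(SimulationConfig(dispersion = -1), "dispersion",
               class = "cortex_config_error")
  expect_error(SimulationConfig(depthFactors = c(1, 1)), "depthFactors",
               class = "cortex_config_error")
  expect_error(SimulationConfig(fractionDa = 0.7,
                                fractionConditionSpecific = 0.6),
               class = "cortex_config_error")
  expect_error(SimulationConfig(baselineLogMean = NaN), "baselineLogMean",
               class = "cortex_config_error")
})

test_that("simulated contours hit their constructed shape values", {
  circ <- simulateContour(1, nVertices = 4096)
  expect_lt(abs(circularity(circ) - 1), 1e-4)
  ell <- simulateContour(2, nVertices = 1024)
  expect_lt(abs(aspectRatio(ell) - 2) / 2, 0.01)
  # determinism, with and without noise
  expect_identical(vertices(simulateContour(1.5, 64)),
                   vertices(simulateContour(1.5, 64)))
  n1 <- simulateContour(1.5, 64, noiseSd = 0.3, seed = 4)
  expect_identical(vertices(n1),
                   vertices(simulateContour(1.5, 64, noiseSd = 0.3, seed = 4)))
  expect_false(identical(vertices(n1),
                         vertices(simulateContour(1.5, 64, noiseSd = 0.3,
                                                  seed = 5))))
  expect_error(simulateContour(1, nVertices = 4),
               class = "cortex_config_error")
  expect_error(simulateContour(0.5), class = "cortex_config_error")
})

test_that("division timelines realise the requested durations", {
  cases <- list(list(5L, 5L, 2, 10, 10),
                list(0L, 3L, 2, 0, 6),
                list(5L, 5L, 1, 5, 5))
  for (cs in cases) {
    ev <- simulateDivisionTimeline(cs[[1]], cs[[2]], frameIntervalMin = cs[[3]])
    expect_equal(roundingTime(ev), cs[[4]])
    expect_equal(ingressionTime(ev), cs[[5]])
  }
  expect_error(simulateDivisionTimeline(-1L, 3L),
               class = "cortex_config_error")
  expect_error(DivisionEvents(5L, 4L, 10L, 12L))
})
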