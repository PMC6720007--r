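test_that("every generator is bit-identical under a fixed seed", {
  cfg <- simulationConfig(nMirnas = 80, nGenes = 60, nCommunities = 3,
                          seed = 42)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(a$experiment),
                   SummarizedExperiment::assay(b$experiment))
  expect_identical(a$truth@deMirnas, b$truth@deMirnas)
  expect_identical(simulateTargetTables(cfg, a$truth),
                   simulateTargetTables(cfg, b$truth))
  expect_identical(simulatePPI(cfg, a$truth), simulatePPI(cfg, b$truth))
  expect_identical(simulateGeneSets(a$truth, seed = 9),
                   simulateGeneSets(b$truth, seed = 9))
  expect_identical(simulateSerum(cfg), simulateSerum(cfg))
})

test_that("expression matrix has the cohort shape and honours fracDE = 0", {
  cfg <- simulationConfig(nCases = 19, nControls = 19, nMirnas = 50)
  sim <- simulateExpression(cfg)
  expect_equal(ncol(sim$experiment), 38L)
  expect_equal(nrow(sim$experiment), 50L + cfg@nNegctrlProbes)

  none <- simulateExpression(simulationConfig(fracDE = 0, nMirnas = 50))
  expect_equal(nrow(none$truth@deMirnas), 0L)
  expect_length(none$truth@candidateMirna, 0L)
})

test_that("planted group-mean differences match the ground truth", {
  cfg <- simulationConfig(seed = 1, nMirnas = 500, fracDE = 0.1,
                          deLog2fcMagnitude = 1.0, withinGroupSd = 0.5)
  sim <- simulateExpression(cfg)
  mat <- SummarizedExperiment::assay(sim$experiment)
  grp <- sampleGroups(sim$experiment)
  truth <- sim$truth@deMirnas
  for (i in seq_len(nrow(truth))) {
    v <- mat[truth$mirna[i], ]
    x <- v[grp == "case"]; y <- v[grp == "control"]
    diff <- mean(x) - mean(y)
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    expect_lt(abs(diff - truth$log2fc[i]), 3 * se)
  }
  # non-candidate planted effects sit at +/- the configured magnitude
  other <- truth[truth$mirna != sim$truth@candidateMirna, ]
  expect_true(all(abs(other$log2fc) == 1.0))
  cand <- truth[truth$mirna == sim$truth@candidateMirna, ]
  expect_equal(cand$log2fc, -2.0)
})

test_that("source agreement controls true-edge reporting", {
  cfg1 <- simulationConfig(nMirnas = 60, nGenes = 60, sourceAgreement = 1)
  sim <- simulateExpression(cfg1)
  tabs <- simulateTargetTables(cfg1, sim$truth)
  trueKeys <- paste(sim$truth@trueEdges$mirna, sim$truth@trueEdges$gene)
  for (tab in tabs)
    expect_true(all(trueKeys %in% paste(tab$mirna, tab$gene)))

  cfg0 <- simulationConfig(nMirnas = 60, nGenes = 60, sourceAgreement = 0)
  sim0 <- simulateExpression(cfg0)
  tabs0 <- simulateTargetTables(cfg0, sim0$truth)
  trueKeys0 <- paste(sim0$truth@trueEdges$mirna, sim0$truth@trueEdges$gene)
  for (tab in tabs0)
    expect_false(any(trueKeys0 %in% paste(tab$mirna, tab$gene)))

  expect_error(
    simulateTargetTables(simulationConfig(nSources = 1),
                         sim$truth),
    "nSources")
})

test_that("fraction of true edges in >= 2 of 3 sources matches the binomial closed form", {
  cfg <- simulationConfig(seed = 7, nSources = 3, sourceAgreement = 0.8)
  sim <- simulateExpression(cfg)
  tabs <- simulateTargetTables(cfg, sim$truth)
  te <- sim$truth@trueEdges
  keys <- paste(te$mirna, te$gene)
  support <- Reduce(`+`, lapply(tabs, function(tab)
    keys %in% paste(tab$mirna, tab$gene)))
  frac <- mean(support >= 2)
  p <- 3 * 0.8^2 * 0.2 + 0.8^3   # = 0.896
  ci <- 2.576 * sqrt(p * (1 - p) / length(keys))
  expect_lt(abs(frac - p), ci + 1e-9)
})

test_that("planted-partition PPI graph has the prescribed structure", {
  cfg <- simulationConfig(nGenes = 20, nCommunities = 2, pWithin = 1,
                          pBetween = 0)
  sim <- simulateExpression(cfg)
  ppi <- simulatePPI(cfg, sim$truth)
  comm <- sim$truth@communityOfGene
  # two disjoint cliques: every within pair present, no between pair
  expect_true(all(comm[ppi$gene_a] == comm[ppi$gene_b]))
  sizes <- table(comm)
  expect_equal(nrow(ppi), sum(choose(sizes, 2)))
  expect_true(all(ppi$gene_a != ppi$gene_b))
  expect_false(any(duplicated(paste(pmin(ppi$gene_a, ppi$gene_b),
                                    pmax(ppi$gene_a, ppi$gene_b)))))

  # near-uniform probabilities: edge count within the binomial 99% CI
  cfgU <- simulationConfig(nGenes = 80, nCommunities = 4,
                           pWithin = 0.1 + 1e-9, pBetween = 0.1, seed = 5)
  simU <- simulateExpression(cfgU)
  ppiU <- simulatePPI(cfgU, simU$truth)
  nPairs <- choose(80, 2)
  expected <- 0.1 * nPairs
  ci <- 2.576 * sqrt(nPairs * 0.1 * 0.9)
  expect_lt(abs(nrow(ppiU) - expected), ci)
})

test_that("gene sets mirror the planted communities", {
  cfg <- simulationConfig(nGenes = 60, nCommunities = 3)
  sim <- simulateExpression(cfg)
  sets <- simulateGeneSets(sim$truth, nDecoySets = 0)
  expect_length(sets, 3L)
  comm <- sim$truth@communityOfGene
  for (k in 1:3)
    expect_setequal(sets[[sprintf("community_%d", k)]],
                    names(comm)[comm == k])
  withDecoys <- simulateGeneSets(sim$truth, nDecoySets = 5)
  expect_length(withDecoys, 8L)
})

test_that("serum generator is AUC-calibrated and rejects non-informative targets", {
  expect_error(simulationConfig(targetAuc = 0.5), "targetAuc")
  expect_error(simulationConfig(targetAuc = 0.3), "targetAuc")

  cfg <- simulationConfig(nSerumCases = 1000, nSerumControls = 1000,
                          targetAuc = 0.87, serumSdLog = 0.6)
  serum <- simulateSerum(cfg, seed = 3)
  expect_true(all(serum$level > 0))
  expect_lt(abs(auc(rocAnalysis(serum)) - 0.87), 0.03)

  # paper-shaped cohort and a diameter covariate coupled to the level
  small <- simulateSerum(simulationConfig())
  expect_equal(table(small$group)[["case"]], 28L)
  expect_equal(table(small$group)[["control"]], 20L)
  expect_gt(correlateCovariate(small)$rho, 0)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(simulationConfig(nCases = 1), "nCases")
  expect_error(simulationConfig(fracDE = 1.5), "fracDE")
  expect_error(simulationConfig(pWithin = 0.1, pBetween = 0.2), "pWithin")
  expect_error(simulationConfig(withinGroupSd = -1), "withinGroupSd")
  expect_error(simulationConfig(bogus = 1), "bogus")
})
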