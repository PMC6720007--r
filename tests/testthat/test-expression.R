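makeExperiment <- function(mat, group, negctrl) {
  MirnaExperiment(mat, group = group, isNegativeControl = negctrl)
}

test_that("detection filter keeps rows above the per-sample control threshold", {
  # 38 samples; negative controls at 0 so the 0.9-quantile threshold is 0
  set.seed(1)
  ns <- 38L
  mat <- rbind(
    allAbove = rep(1, ns),
    tenOf38 = c(rep(1, 10), rep(-1, 28)),
    negctrl1 = rep(0, ns),
    negctrl2 = rep(0, ns)
  )
  colnames(mat) <- paste0("s", seq_len(ns))
  x <- makeExperiment(mat, rep(c("case", "control"), each = 19),
                      c(FALSE, FALSE, TRUE, TRUE))
  kept <- detectionFilter(x, minSampleFrac = 0.5)
  expect_identical(rownames(kept), "allAbove")
  expect_false(any(isNegativeControl(kept)))
})

test_that("detection filter equals a brute-force per-row count on simulated data", {
  cfg <- simulationConfig(nMirnas = 200, detectionDropoutRate = 0.4, seed = 8)
  sim <- simulateExpression(cfg)
  x <- sim$experiment
  mat <- SummarizedExperiment::assay(x)
  neg <- isNegativeControl(x)
  thr <- apply(mat[neg, ], 2, quantile, probs = 0.9, names = FALSE)
  expectKeep <- vapply(which(!neg), function(i)
    sum(mat[i, ] > thr) >= 0.5 * ncol(mat), logical(1))
  kept <- detectionFilter(x, minSampleFrac = 0.5, negctrlQuantile = 0.9)
  expect_identical(rownames(kept), rownames(mat)[!neg][expectKeep])

  noNeg <- x[!neg, ]
  expect_error(detectionFilter(noNeg), "negative-control")
})

test_that("Benjamini-Hochberg matches the step-up formula and is permutation-invariant", {
  expect_equal(benjaminiHochberg(0.03), 0.03)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(benjaminiHochberg(p)[perm], benjaminiHochberg(p[perm]))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential expression agrees with per-row reference tests", {
  cfg <- simulationConfig(nMirnas = 40, detectionDropoutRate = 0, seed = 2)
  sim <- simulateExpression(cfg)
  x <- sim$experiment[!isNegativeControl(sim$experiment), ]
  mat <- SummarizedExperiment::assay(x)
  grp <- sampleGroups(x)

  de <- differentialExpression(x)
  # log2fc and mean expression recomputed directly
  expect_equal(de$log2fc,
               unname(rowMeans(mat[, grp == "case"]) -
                        rowMeans(mat[, grp == "control"])))
  expect_equal(de$mean_expression, unname(rowMeans(mat)))
  # Welch p per row against stats::t.test
  pref <- apply(mat, 1, function(v)
    t.test(v[grp == "case"], v[grp == "control"])$p.value)
  expect_equal(de$p_value, unname(pref), tolerance = 1e-12)
  expect_equal(de$q_value, p.adjust(de$p_value, "BH"))
  # cutoff flag equals independent set logic
  expect_equal(de$passes_cutoffs,
               de$q_value < 0.05 & abs(de$log2fc) > 0.5 &
                 de$mean_expression > 5)
  expect_equal(de$direction, ifelse(de$log2fc > 0, "up", "down"))

  mw <- differentialExpression(x, method = "mannwhitney")
  pref2 <- apply(mat, 1, function(v)
    wilcox.test(v[grp == "case"], v[grp == "control"],
                exact = FALSE, correct = TRUE)$p.value)
  expect_equal(mw$p_value, unname(pref2), tolerance = 1e-12)
})

test_that("identical groups yield zero fold changes and no calls", {
  half <- matrix(rnorm(20 * 3, 7), 20, 3)
  mat <- cbind(half, half)
  dimnames(mat) <- list(paste0("m", 1:20), paste0("s", 1:6))
  x <- makeExperiment(mat, rep(c("case", "control"), each = 3),
                      rep(FALSE, 20))
  de <- differentialExpression(x)
  expect_true(all(de$log2fc == 0))
  expect_false(any(de$passes_cutoffs))

  oneCase <- x[, c(1, 4, 5, 6)]
  expect_error(differentialExpression(oneCase), "2 samples")
})

test_that("PCA matches a direct eigendecomposition and conserves variance", {
  set.seed(4)
  mat <- matrix(rnorm(30 * 6, 7), 30, 6,
                dimnames = list(paste0("m", 1:30), paste0("s", 1:6)))
  x <- makeExperiment(mat, rep(c("case", "control"), each = 3),
                      rep(FALSE, 30))
  pc <- expressionPCA(x, k = 6)
  expect_true(all(diff(pc$varianceExplained) <= 1e-12))
  expect_equal(sum(pc$varianceExplained), 1)
  # scores reproduce the eigenvalues of the sample covariance matrix
  ev <- eigen(cov(scale(t(mat), scale = FALSE)), symmetric = TRUE)$values
  expect_equal(unname(apply(pc$scores, 2, var))[1:5], ev[1:5],
               tolerance = 1e-8)

  # duplicated samples collapse to identical score vectors
  mat2 <- mat; mat2[, 2] <- mat2[, 1]
  x2 <- makeExperiment(mat2, rep(c("case", "control"), each = 3),
                       rep(FALSE, 30))
  pc2 <- expressionPCA(x2, k = 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  expect_error(expressionPCA(x, k = 10), "exceeds")
})

test_that("probe collapse takes the per-miRNA median", {
  mat <- matrix(c(1, 3, 5,
                  2, 4, 6,
                  10, 10, 10,
                  0, 0, 0,
                  0, 0, 0), 5, 3, byrow = TRUE,
                dimnames = list(paste0("p", 1:5), paste0("s", 1:3)))
  mat <- cbind(mat, mat)
  colnames(mat) <- paste0("s", 1:6)
  x <- MirnaExperiment(mat, group = rep(c("case", "control"), each = 3),
                       isNegativeControl = c(rep(FALSE, 3), TRUE, TRUE),
                       rowData = data.frame(
                         mirna = c("mirA", "mirA", "mirB", NA, NA)))
  y <- collapseProbes(x)
  m <- SummarizedExperiment::assay(y)
  expect_equal(unname(m["mirA", 1:3]), c(1.5, 3.5, 5.5))
  expect_equal(unname(m["mirB", 1:3]), c(10, 10, 10))
  expect_equal(sum(isNegativeControl(y)), 2L)
})
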