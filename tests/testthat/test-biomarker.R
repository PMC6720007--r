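test_that("group comparison reports the median fold change and gates on normality", {
  ctrl <- seq(1, 2, length.out = 10)
  tab <- data.frame(group = rep(c("case", "control"), each = 10),
                    level = c(3 * ctrl, ctrl))
  cmp <- compareGroups(tab)
  expect_equal(cmp$fold_change, 3)
  expect_lt(cmp$p_value, 0.01)

  # identical groups: fold change 1, p ~ 1
  set.seed(51)
  v <- rnorm(12, 10, 1)
  same <- data.frame(group = rep(c("case", "control"), each = 12),
                     level = c(v, v))
  cmpSame <- compareGroups(same)
  expect_equal(cmpSame$fold_change, 1)
  expect_gt(cmpSame$p_value, 0.99)
  expect_equal(cmpSame$test, "t")   # normal draws pass the gate

  # heavy right skew fails Shapiro-Wilk -> Mann-Whitney branch
  set.seed(52)
  skew <- data.frame(group = rep(c("case", "control"), each = 30),
                     level = exp(rnorm(60, 0, 1.5)))
  expect_equal(compareGroups(skew)$test, "mannwhitney")

  expect_error(compareGroups(data.frame(group = "case", level = -1)),
               "positive|group")
  expect_error(
    compareGroups(data.frame(group = rep(c("case", "control"), c(2, 5)),
                             level = 1:7)),
    ">= 3")
})

test_that("ROC handles perfect separation and random labels", {
  sep <- data.frame(group = rep(c("case", "control"), each = 5),
                    level = c(10:14, 1:5))
  r <- rocAnalysis(sep)
  expect_equal(auc(r), 1)
  yp <- youdenPoint(r)
  expect_equal(unname(yp["sensitivity"]), 1)
  expect_equal(unname(yp["specificity"]), 1)

  set.seed(53)
  rnd <- data.frame(group = sample(rep(c("case", "control"), each = 1000)),
                    level = rexp(2000))
  expect_lt(abs(auc(rocAnalysis(rnd)) - 0.5), 0.05)

  expect_error(rocAnalysis(data.frame(group = rep("case", 4),
                                      level = 1:4)),
               "group|class")
})

test_that("trapezoidal AUC equals the tie-corrected rank-sum statistic", {
  set.seed(54)
  for (i in 1:60) {
    tab <- randomBiomarkerTable(sample(5:25, 1), sample(5:25, 1),
                                values = seq(0.5, 5, by = 0.5))  # many ties
    r <- rocAnalysis(tab)
    expect_equal(auc(r),
                 rankSumAUC(tab$level[tab$group == "case"],
                            tab$level[tab$group == "control"]),
                 tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly increasing transforms and flips under decreasing ones", {
  set.seed(55)
  tab <- randomBiomarkerTable(20, 15, values = c(1, 2, 2, 3, 5, 8))
  r <- rocAnalysis(tab)
  up <- tab; up$level <- tab$level^3
  rUp <- rocAnalysis(up)
  expect_equal(auc(rUp), auc(r), tolerance = 1e-12)
  expect_equal(rUp@sensitivityAtYouden, r@sensitivityAtYouden)
  expect_equal(rUp@specificityAtYouden, r@specificityAtYouden)

  down <- tab; down$level <- 1 / tab$level
  expect_equal(auc(rocAnalysis(down)), 1 - auc(r), tolerance = 1e-12)
})

test_that("median split puts the median case in the low group", {
  tab <- data.frame(subject_id = paste0("s", 1:7),
                    group = c(rep("case", 5), "control", "control"),
                    level = 1:7,
                    diameter_mm = c(41, 55, 49, 60, 45, NA, NA))
  sp <- subgroupByMedian(tab)
  expect_equal(sp$cutpoint, 49)
  expect_equal(sort(sp$low$subject_id), c("s1", "s3", "s5"))  # <= 49
  expect_equal(sort(sp$high$subject_id), c("s2", "s4"))

  const <- tab; const$diameter_mm[1:5] <- 50
  spc <- subgroupByMedian(const)
  expect_equal(nrow(spc$low), 5L)
  expect_equal(nrow(spc$high), 0L)

  miss <- tab; miss$diameter_mm[2] <- NA
  expect_error(subgroupByMedian(miss), "s2")
})

test_that("Spearman correlation matches rank-then-Pearson with ties", {
  inc <- data.frame(group = rep("case", 5), level = c(1, 2, 3, 4, 5),
                    diameter_mm = c(10, 20, 30, 40, 50))
  inc$group <- c("case", "case", "case", "control", "control")
  expect_equal(correlateCovariate(inc)$rho, 1)
  dec <- inc; dec$diameter_mm <- rev(dec$diameter_mm)
  expect_equal(correlateCovariate(dec)$rho, -1)

  tie <- data.frame(group = rep(c("case", "control"), each = 3),
                    level = c(1, 2, 2, 3, 4, 5),
                    diameter_mm = c(5, 7, 6, 6, 9, 10))
  got <- correlateCovariate(tie)
  expect_equal(got$rho, cor(rank(tie$level), rank(tie$diameter_mm)),
               tolerance = 1e-12)

  const <- data.frame(group = rep(c("case", "control"), each = 3),
                      level = rep(2, 6), diameter_mm = 1:6)
  expect_error(correlateCovariate(const), "constant")
  expect_error(correlateCovariate(inc[1:3, ]), ">= 4")
})
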