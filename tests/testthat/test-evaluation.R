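test_that("group summaries aggregate AUCs, frequencies and raw-scale ORs", {
  gr <- fakeGroupResult(rep(0.7, 20))
  s <- summarizeGroup(gr)
  expect_equal(s$aucMean, 0.7)
  expect_equal(s$aucSD, 0)
  expect_equal(s$aucP10, 0.7)
  expect_equal(s$aucP90, 0.7)
  # f1 selected in every split with beta = ln 2 and bounds (0, 1): OR = 2
  expect_equal(unname(s$selectionFrequency["f1"]), 1)
  expect_equal(s$orTable$orMedian[s$orTable$feature == "f1"], 2)
  # partial selection: zeros from non-selection enter the OR percentiles
  gr2 <- fakeGroupResult(runif(10, 0.6, 0.8))
  for (k in c(2, 5, 8)) {
    gr2@splits[[k]]$coefficients <- c(f1 = 0)
    gr2@splits[[k]]$selected <- character(0)
  }
  s2 <- summarizeGroup(gr2)
  expect_equal(unname(s2$selectionFrequency["f1"]), 0.7)
  expect_equal(s2$orTable$orP10[1], 0)        # zeros pulled the 10th percentile
  s2x <- summarizeGroup(gr2, orIncludeZeros = FALSE)
  expect_equal(s2x$orTable$orP10[1], 2)       # excluded instead
  # permutation invariance over splits
  gr3 <- fakeGroupResult(seq(0.5, 0.9, length.out = 9))
  gr4 <- gr3
  gr4@splits <- gr4@splits[sample(9)]
  s3 <- summarizeGroup(gr3); s4 <- summarizeGroup(gr4)
  expect_equal(s3[c("aucMean", "aucSD", "aucP10", "aucP90")],
               s4[c("aucMean", "aucSD", "aucP10", "aucP90")])
})

test_that("group comparison z-test handles degenerate and planted cases", {
  a <- fakeGroupResult(seq(0.55, 0.75, length.out = 50))
  expect_equal(compareGroups(a, a)$pValue, 1)             # identical groups
  b <- fakeGroupResult(testAUCs(a) + 0.05)
  expect_warning(cmp <- compareGroups(b, a), "zero-variance")
  expect_equal(cmp$pValue, 0)
  # planted moments, uncorrected statistic: mean gap 0.05, sd 0.11, n = 1000
  set.seed(50)
  base <- pmin(pmax(rnorm(1000, 0.65, 0.08), 0.3), 0.95)
  delta <- rnorm(1000, 0.05, 0.11)
  g1 <- fakeGroupResult(base, tag = "DO")
  g2 <- fakeGroupResult(pmin(pmax(base - delta, 0), 1), tag = "DVH")
  cmp <- compareGroups(g1, g2, correction = "none")
  expect_lt(cmp$pValue, 0.01)
  expect_gt(cmp$statistic, 0)
  # the resampling-corrected default shrinks the same statistic by
  # sqrt(1 + n * nTest/nTrain) but never changes its sign
  cmpC <- compareGroups(g1, g2)
  expect_equal(cmpC$statistic,
               cmp$statistic / sqrt(1 + 1000 * 0.25), tolerance = 1e-10)
  expect_gt(cmpC$pValue, cmp$pValue)
  # paired and unpaired statistics agree in sign
  cmpU <- compareGroups(g1, g2, paired = FALSE)
  expect_equal(sign(cmpU$statistic), sign(cmp$statistic))
  expect_error(compareGroups(g1, fakeGroupResult(rep(0.5, 7))), "split counts")
})

test_that("modality chi-square matches Pearson hand calculations", {
  prop <- matrix(c(30, 15, 10, 5), 2)       # perfectly proportional
  r <- modalityOutcomeChisq(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$pValue, 1, tolerance = 1e-12)
  expect_equal(modalityOutcomeChisq(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  r2 <- modalityOutcomeChisq(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-10)   # 6.666...
  expect_equal(r2$pValue, 0.009823, tolerance = 1e-3)
  expect_equal(r2$df, 1)
})

test_that("mean ROC curves are monotone and hit known anchors", {
  # one split with a perfect classifier passes through (0, 1)
  gr <- fakeGroupResult(1, scores = list(c(0.1, 0.9, 0.2, 0.8)),
                        labels = list(c(0, 1, 0, 1)))
  roc <- rocCurveMean(gr)
  expect_equal(nrow(roc), 101L)
  expect_equal(roc$meanTpr[roc$fpr == 0], 1)
  expect_true(all(diff(roc$meanTpr) >= -1e-12))
  # random scores average out to the diagonal
  set.seed(51)
  n <- 40
  scores <- replicate(150, rnorm(n), simplify = FALSE)
  labels <- replicate(150, rbinom(n, 1, 0.5), simplify = FALSE)
  aucs <- mapply(aucFromScores, scores, labels)
  grr <- fakeGroupResult(aucs, scores = scores, labels = labels)
  rocr <- rocCurveMean(grr)
  mid <- rocr[rocr$fpr > 0.2 & rocr$fpr < 0.8, ]
  expect_lt(max(abs(mid$meanTpr - mid$fpr)), 0.08)
})
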