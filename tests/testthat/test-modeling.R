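makeTable <- function(X, y, tag = "DO") FeatureTable(X, y, tag)

test_that("the Spearman filter drops later features correlated > threshold", {
  set.seed(40)
  f1 <- rnorm(30)
  f3 <- rnorm(30)
  X <- cbind(f1 = f1, f2 = 2 * f1, f3 = f3)
  tab <- makeTable(X, rep(c(0L, 1L), 15))
  kept <- spearmanRedundancyFilter(tab, 0.8)
  expect_identical(featureNames(kept), c("f1", "f3"))
  # weakly correlated table passes unchanged, order preserved
  X2 <- matrix(rnorm(300), 30)
  colnames(X2) <- paste0("g", 1:10)
  tab2 <- makeTable(X2, rep(c(0L, 1L), 15))
  expect_identical(featureNames(spearmanRedundancyFilter(tab2, 0.8)),
                   colnames(X2))
  # constant feature: undefined rho, kept with a warning
  X3 <- cbind(c1 = rep(1, 30), f1 = f1)
  expect_warning(kept3 <- spearmanRedundancyFilter(
    makeTable(X3, rep(c(0L, 1L), 15)), 0.8), "constant")
  expect_identical(featureNames(kept3), c("c1", "f1"))
})

test_that("min-max normalization uses train bounds and does not clip", {
  tr <- cbind(a = c(2, 4, 6), b = c(0, 1, 2))
  te <- cbind(a = c(8, 2), b = c(1, -1))
  nm <- minmaxNormalize(tr, te)
  expect_equal(unname(nm$train[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nm$applied[, "a"]), c(1.5, 0))   # extrapolated, unclipped
  expect_equal(unname(nm$applied[, "b"]), c(0.5, -0.5))
  expect_equal(unname(nm$bounds[, "a"]), c(2, 6))
  expect_warning(nc <- minmaxNormalize(cbind(k = c(3, 3, 3))), "constant")
  expect_true(all(nc$train == 0))
})

test_that("minority oversampling balances classes deterministically", {
  X <- matrix(seq_len(28), 14, 2)
  y <- c(rep(0L, 10), rep(1L, 4))
  set.seed(41)
  os <- oversampleMinority(X, y)
  expect_equal(sum(os$y == 0), 10)
  expect_equal(sum(os$y == 1), 10)
  expect_identical(os$rowIndex[1:14], 1:14)          # originals untouched
  expect_true(all(os$rowIndex[15:20] %in% 11:14))    # extras from minority
  bal <- oversampleMinority(X[c(1:4, 11:14), ], y[c(1:4, 11:14)])
  expect_identical(bal$rowIndex, 1:8)                # already balanced
  set.seed(41)
  os2 <- oversampleMinority(X, y)
  expect_identical(os$rowIndex, os2$rowIndex)        # seeded determinism
})

test_that("full shrinkage zeroes all coefficients on balanced classes", {
  d <- logisticToy()
  os <- list(X = d$X, y = d$y)
  set.seed(42)
  bal <- oversampleMinority(d$X, d$y)
  fit <- fitLassoLogistic(bal$X, bal$y, C = 1e-8)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_length(fit$selected, 0L)
})

test_that("a duplicated column shares the single-column fit's coefficient", {
  d <- logisticToy(n = 120, pNoise = 0, beta = 4)
  single <- fitLassoLogistic(d$X[, "signal", drop = FALSE], d$y, C = 1)
  dup <- fitLassoLogistic(cbind(s1 = d$X[, 1], s2 = d$X[, 1]), d$y, C = 1)
  expect_equal(sum(dup$coefficients), unname(single$coefficients["signal"]),
               tolerance = 1e-4)
})

test_that("a separating feature is selected with a positive coefficient", {
  x <- cbind(f = c(runif(20, 0, 0.4), runif(20, 0.6, 1)))
  y <- rep(c(0L, 1L), each = 20)
  fit <- fitLassoLogistic(x, y, C = 10)
  expect_identical(fit$selected, "f")
  expect_gt(fit$coefficients["f"], 0)
})

test_that("stronger penalties never select more features", {
  d <- logisticToy(n = 100, pNoise = 8, beta = 3, seed = 44)
  grid <- 10^seq(-3, 3, length.out = 13)
  nsel <- vapply(grid, function(C)
    length(fitLassoLogistic(d$X, d$y, C)$selected), integer(1))
  expect_true(all(diff(nsel) >= 0))  # grid is ascending in C (weaker penalty)
})

test_that("tuning returns the grid value itself for a one-point grid", {
  d <- logisticToy()
  cfg <- deskModelingConfig(regGrid = 0.5)
  set.seed(45)
  expect_equal(tuneRegularization(d$X, d$y, cfg)$C, 0.5)
})

test_that("pure-noise features tune to the strong-penalty end of the grid", {
  set.seed(46)
  hits <- replicate(10, {
    X <- matrix(rnorm(60 * 6), 60)
    colnames(X) <- paste0("n", 1:6)
    y <- rbinom(60, 1, 0.5)
    cfg <- deskModelingConfig(cvRounds = 2)
    tuneRegularization(X, y, cfg)$C
  })
  # majority of replicates land in the strongest third of the grid
  expect_gte(mean(hits <= 10^(-2/3)), 0.6)
})

test_that("runGroup yields valid, deterministic, auditable results", {
  set.seed(47)
  X <- matrix(rnorm(40 * 5), 40)
  colnames(X) <- paste0("f", 1:5)
  X[, 1] <- X[, 1] + rep(c(0, 1.6), each = 20)
  y <- rep(c(0L, 1L), each = 20)
  tab <- makeTable(X, y, "DVH")
  cfg <- deskModelingConfig(nSplits = 6, cvRounds = 1,
                            regGrid = 10^seq(-1, 1, length.out = 3), seed = 9)
  gr <- suppressWarnings(runGroup(tab, cfg))
  expect_s4_class(gr, "GroupResult")
  expect_length(splitResults(gr), 6L)
  aucs <- testAUCs(gr)
  expect_true(all(aucs >= 0 & aucs <= 1))
  # bit-identical rerun under the same master seed
  gr2 <- suppressWarnings(runGroup(tab, cfg))
  expect_identical(splitResults(gr), splitResults(gr2))
  # leakage audit: replaying any split from its stored seed reproduces it
  for (k in c(1L, 4L)) {
    replay <- suppressWarnings(refitSplit(tab, gr, k))
    expect_identical(replay$coefficients, splitResults(gr)[[k]]$coefficients)
    expect_identical(replay$trainIdx, splitResults(gr)[[k]]$trainIdx)
    expect_equal(replay$testAUC, splitResults(gr)[[k]]$testAUC)
  }
  # training AUC of the fitted model is at least the null model's 0.5
  s1 <- splitResults(gr)[[1]]
  nm <- minmaxNormalize(X[s1$trainIdx, ], X[s1$trainIdx, ])
  trainScores <- as.numeric(nm$applied %*% s1$coefficients + s1$intercept)
  expect_gte(aucFromScores(trainScores, y[s1$trainIdx]), 0.5)
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(48)
  for (i in 1:5) {
    sc <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(aucFromScores(sc, y),
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))),
                 tolerance = 1e-12)
  }
})

test_that("null-label groups hover near AUC 0.5", {
  set.seed(49)
  X <- matrix(rnorm(50 * 6), 50)
  colnames(X) <- paste0("f", 1:6)
  y <- rbinom(50, 1, 0.6)
  cfg <- deskModelingConfig(nSplits = 60, cvRounds = 1,
                            regGrid = 10^seq(-2, 2, length.out = 5), seed = 13)
  gr <- suppressWarnings(runGroup(makeTable(X, y), cfg))
  aucs <- testAUCs(gr)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.05)
})
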