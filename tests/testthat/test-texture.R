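test_that("discretization follows the floor rule, clamps and warns", {
  g <- DoseGrid(array(c(0.2, 0.9, 1.0, 2.7), c(4, 1, 1)))
  m <- RoiMask(array(1, c(4, 1, 1)))
  q <- discretizeDose(g, m, discretizationSpec(binWidth = 1))
  expect_identical(as.vector(gridValues(q)), c(1L, 1L, 2L, 3L))
  # uniform dose occupies a single level
  qu <- discretizeDose(uniformGrid(12.3), fullMask())
  expect_identical(unique(as.vector(gridValues(qu))[gridValues(qu) > 0]), 13L)
  # above-range doses clamp to the top level with a warning
  hot <- uniformGrid(150)
  expect_warning(qh <- discretizeDose(hot, fullMask()), "clamped")
  expect_identical(max(gridValues(qh)), 100L)
  # out-of-mask voxels are level 0
  m2 <- RoiMask(array(c(1, 0, 1, 0), c(4, 1, 1)))
  q2 <- discretizeDose(g, m2)
  expect_identical(as.vector(gridValues(q2))[c(2, 4)], c(0L, 0L))
})

test_that("first-order statistics match closed forms", {
  # constant volume: degenerate moments are zeroed
  f <- firstOrderFeatures(uniformGrid(7), fullMask())
  expect_length(f, 18L)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Skewness"]), 0)
  expect_equal(unname(f["firstorder_Kurtosis"]), 0)
  expect_equal(unname(f["firstorder_Range"]), 0)
  expect_equal(unname(f["firstorder_Mean"]), 7)
  expect_equal(unname(f["firstorder_Median"]), 7)
  # 100 equally represented dose bands at bin centres
  g <- DoseGrid(array(seq(0.5, 99.5, by = 1), c(100, 1, 1)))
  m <- RoiMask(array(1, c(100, 1, 1)))
  f <- firstOrderFeatures(g, m)
  expect_equal(unname(f["firstorder_Uniformity"]), 1 / 100, tolerance = 1e-12)
  # linear-interpolated order statistic: 89.5 + 0.1 * (90.5 - 89.5)
  expect_equal(unname(f["firstorder_Percentile90"]), 89.6, tolerance = 1e-12)
  expect_equal(unname(f["firstorder_Entropy"]), log2(100), tolerance = 1e-12)
  # two-voxel example {0, 4}
  pair <- DoseGrid(array(c(0, 4), c(2, 1, 1)), spacing = c(2, 2, 2))
  m2 <- RoiMask(array(1, c(2, 1, 1)), spacing = c(2, 2, 2))
  f2 <- firstOrderFeatures(pair, m2)
  expect_equal(unname(f2["firstorder_Mean"]), 2)
  expect_equal(unname(f2["firstorder_RootMeanSquared"]), sqrt(8))
  expect_equal(unname(f2["firstorder_Energy"]), 16)
  expect_equal(unname(f2["firstorder_TotalEnergy"]), 8 * 16)
  # mean/variance against a two-pass reference
  set.seed(30)
  r <- randomGrid(c(6, 6, 6))
  rm <- randomMask(c(6, 6, 6))
  x <- gridValues(r)[gridValues(rm) > 0.5]
  fr <- firstOrderFeatures(r, rm)
  expect_equal(unname(fr["firstorder_Mean"]), mean(x), tolerance = 1e-10)
  expect_equal(unname(fr["firstorder_Variance"]),
               mean((x - mean(x))^2), tolerance = 1e-10)
})

test_that("GLCM counts equal brute-force pair enumeration", {
  set.seed(31)
  for (i in 1:6) {
    lv <- array(sample(0:4, 5 * 4 * 3, replace = TRUE), c(5, 4, 3))
    if (max(lv) == 0) next
    counts <- dosiomics:::.cppGlcmCounts(as.integer(lv), dim(lv),
                                         max(lv))
    expect_identical(as.vector(counts), as.vector(oracleGlcm(lv, max(lv))))
  }
  # checkerboard slab: every in-plane x/y neighbour pair differs by one level
  lv <- array(0L, c(4, 4, 1))
  lv[, , 1] <- (outer(1:4, 1:4, `+`) %% 2L) + 1L
  counts <- dosiomics:::.cppGlcmCounts(as.integer(lv), dim(lv), 2L)
  for (d in 1:2) {                      # (1,0,0) and (0,1,0)
    P <- counts[, , d] / sum(counts[, , d])
    expect_equal(sum(abs(row(P) - col(P))^2 * P), 1)  # contrast = 1
  }
  expect_true(all(apply(counts, 3, function(m) isSymmetric(matrix(m, 2)))))
})

test_that("uniform volumes give zero GLCM contrast and normalized matrices", {
  q <- discretizeDose(uniformGrid(20), fullMask())
  f <- suppressWarnings(glcmFeatures(q))
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_Correlation"]), 0)  # degenerate rule
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
  expect_warning(glcmFeatures(q), "degenerate")
})

test_that("GLRLM counts equal brute-force run enumeration", {
  lv <- array(c(1L, 1L, 1L, 2L, 2L), c(1, 1, 5))
  counts <- dosiomics:::.cppGlrlmCounts(as.integer(lv), dim(lv), 2L)
  zdir <- 3  # (0, 0, 1)
  expect_equal(counts[1, 3, zdir], 1L)  # level 1, run length 3
  expect_equal(counts[2, 2, zdir], 1L)  # level 2, run length 2
  expect_identical(as.vector(counts), as.vector(oracleGlrlm(lv, 2L)))
  set.seed(32)
  for (i in 1:6) {
    lv <- array(sample(0:3, 4 * 4 * 4, replace = TRUE), c(4, 4, 4))
    if (max(lv) == 0) next
    counts <- dosiomics:::.cppGlrlmCounts(as.integer(lv), dim(lv), max(lv))
    expect_identical(as.vector(counts), as.vector(oracleGlrlm(lv, max(lv))))
  }
  # all runs of length one: short-run emphasis is exactly 1
  ramp <- quantizedFrom(array(1:5, c(5, 1, 1)))
  f <- glrlmFeatures(ramp)
  expect_equal(unname(f["glrlm_ShortRunEmphasis"]), 1)
  # uniform line: a single maximal run along the line direction
  u <- quantizedFrom(array(1L, c(1, 1, 6)))
  counts <- dosiomics:::.cppGlrlmCounts(as.integer(gridValues(u)),
                                        gridDim(u), 1L)
  expect_equal(counts[1, 6, 3], 1L)
})

test_that("GLSZM zones equal brute-force connected components", {
  # two disjoint blobs of the same level, sizes 3 and 5
  lv <- array(0L, c(7, 3, 2))
  lv[1:3, 1, 1] <- 1L
  lv[5:7, c(2, 3), 1][c(1, 2, 3, 5, 6)] <- 1L
  q <- quantizedFrom(lv)
  z <- packageZonesAsDf(q)
  o <- oracleGlszm(lv)
  expect_equal(z$level, o$level)
  expect_equal(z$size, o$size)
  expect_equal(z$n, o$n)
  expect_setequal(z$size, c(3, 5))
  # uniform volume: one zone covering the mask
  qu <- discretizeDose(uniformGrid(9, c(3, 3, 3)), fullMask(c(3, 3, 3)))
  zu <- packageZonesAsDf(qu)
  expect_equal(nrow(zu), 1L)
  expect_equal(zu$size, 27)
  # all level 1: low-gray-level-zone emphasis is 1 by the 1/i^2 weighting
  f <- suppressWarnings(glszmFeatures(quantizedFrom(array(1L, c(3, 3, 3)))))
  expect_equal(unname(f["glszm_LowGrayLevelZoneEmphasis"]), 1)
  set.seed(33)
  for (i in 1:6) {
    lv <- array(sample(0:3, 5 * 4 * 4, replace = TRUE), c(5, 4, 4))
    if (max(lv) == 0) next
    z <- packageZonesAsDf(quantizedFrom(lv))
    o <- oracleGlszm(lv)
    expect_equal(z, o, ignore_attr = TRUE)
  }
})

test_that("NGTDM accumulators equal brute-force neighbourhood means", {
  # 3x3 plate with level 2 at the centre amid level 1
  lv <- array(1L, c(3, 3, 1))
  lv[2, 2, 1] <- 2L
  m <- dosiomics:::.cppNgtdm(as.integer(lv), dim(lv), 2L)
  o <- oracleNgtdm(lv, 2L)
  expect_equal(m[, 1], o[, "n"])
  expect_equal(m[, 2], o[, "s"])
  expect_equal(m[2, 2], 1)            # s_2 = |2 - 1|
  expect_equal(m[2, 1], 1)            # one voxel of level 2
  set.seed(34)
  for (i in 1:6) {
    lv <- array(sample(0:4, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
    if (max(lv) == 0) next
    m <- dosiomics:::.cppNgtdm(as.integer(lv), dim(lv), max(lv))
    o <- oracleNgtdm(lv, max(lv))
    expect_equal(m[, 1], o[, "n"], tolerance = 1e-12)
    expect_equal(m[, 2], o[, "s"], tolerance = 1e-12)
  }
  # uniform volume: all s_i = 0, busyness falls back to 0 with a warning
  qu <- discretizeDose(uniformGrid(5), fullMask())
  expect_warning(f <- ngtdmFeatures(qu), "degenerate")
  expect_equal(unname(f["ngtdm_Busyness"]), 0)
})

test_that("GLDM dependence counts equal brute force and conserve voxels", {
  # uniform 3x3x3: the centre voxel has all 26 neighbours dependent
  lv <- array(1L, c(3, 3, 3))
  C <- dosiomics:::.cppGldmCounts(as.integer(lv), dim(lv), 1L, 0L)
  expect_equal(C[1, 27], 1L)            # dependence 26 (column d + 1)
  expect_identical(as.vector(C), as.vector(oracleGldm(lv, 1L, 0L)))
  # strictly increasing line with alpha 0: every dependence is 0
  lv <- array(1:6, c(1, 1, 6))
  C <- dosiomics:::.cppGldmCounts(as.integer(lv), dim(lv), 6L, 0L)
  expect_equal(unname(colSums(C)), c(6L, rep(0L, 26)))
  set.seed(35)
  for (i in 1:6) {
    lv <- array(sample(0:4, 4 * 4 * 5, replace = TRUE), c(4, 4, 5))
    if (max(lv) == 0) next
    for (alpha in c(0L, 1L)) {
      C <- dosiomics:::.cppGldmCounts(as.integer(lv), dim(lv), max(lv), alpha)
      expect_identical(as.vector(C), as.vector(oracleGldm(lv, max(lv), alpha)))
      # row sums conserve the per-level voxel counts
      expect_equal(unname(rowSums(C)),
                   tabulate(lv[lv > 0], nbins = max(lv)))
    }
  }
})

test_that("the dosiomic vector is complete, stable and geometry-invariant", {
  set.seed(36)
  g <- randomGrid(c(6, 6, 6), 0, 60)
  m <- randomMask(c(6, 6, 6))
  f <- extractDosiomicFeatures(g, m)
  expect_length(f, 93L)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), dosiomicFeatureNames())
  counts <- table(sub("_.*", "", names(f)))
  expect_identical(unname(counts[c("firstorder", "glcm", "glrlm", "glszm",
                                   "ngtdm", "gldm")]),
                   unname(table(c(rep("a", 18), rep("b", 24), rep("c", 16),
                                  rep("d", 16), rep("e", 5), rep("f", 14)))))
  # translation invariance: shifting the origin changes nothing
  gt <- DoseGrid(gridValues(g), gridSpacing(g), origin = c(50, -20, 3))
  mt <- RoiMask(gridValues(m), gridSpacing(m), origin = c(50, -20, 3))
  expect_identical(extractDosiomicFeatures(gt, mt), f)
  # voxel-storage permutation invariance (axis relabeling)
  perm <- c(2, 3, 1)
  gp <- DoseGrid(aperm(gridValues(g), perm), gridSpacing(g)[perm])
  mp <- RoiMask(aperm(gridValues(m), perm), gridSpacing(m)[perm])
  expect_equal(extractDosiomicFeatures(gp, mp), f, tolerance = 1e-12)
})
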