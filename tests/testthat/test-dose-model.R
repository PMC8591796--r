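test_that("grid classes enforce their invariants", {
  expect_error(DoseGrid(matrix(1, 2, 2)), "3 axes")
  expect_error(DoseGrid(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(DoseGrid(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(RoiMask(array(0, c(2, 2, 2))), "foreground")
  # mask constructor binarizes at > 0.5
  m <- RoiMask(array(c(0.2, 0.7, 1, 0), c(1, 2, 2)))
  expect_identical(sort(unique(as.vector(gridValues(m)))), c(0, 1))
})

test_that("fixture format round-trips values and geometry", {
  g <- randomGrid(c(4, 4, 4))
  p <- file.path(tempdir(), "vol.dgrid")
  writeVolume(g, p)
  g2 <- readVolume(p)
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-12)
  expect_equal(gridSpacing(g2), gridSpacing(g))
  expect_equal(gridDim(g2), c(4L, 4L, 4L))
  m <- randomMask(c(4, 4, 4))
  writeVolume(m, p)
  expect_equal(gridValues(readVolume(p, mask = TRUE)), gridValues(m))
  expect_error(readVolume(file.path(tempdir(), "nope.dgrid")), "not found")
})

test_that("NIfTI and NRRD readers round-trip and validate", {
  g <- DoseGrid(array(runif(60, 0, 50), c(5, 4, 3)),
                spacing = c(1.5, 2, 2.5), origin = c(-10, 5, 0))
  pn <- file.path(tempdir(), "vol.nii.gz")
  writeVolume(g, pn)
  gn <- readVolume(pn)
  expect_equal(gridValues(gn), gridValues(g), tolerance = 1e-6)
  expect_equal(gridSpacing(gn), gridSpacing(g), tolerance = 1e-6)
  pr <- file.path(tempdir(), "vol.nrrd")
  writeVolume(g, pr)
  gr <- readVolume(pr)
  expect_equal(gridValues(gr), gridValues(g), tolerance = 1e-12)
  expect_equal(gridSpacing(gr), gridSpacing(g), tolerance = 1e-9)
  expect_equal(gridOrigin(gr), gridOrigin(g), tolerance = 1e-9)
  # negative voxel in a dose file is rejected on construction
  bad <- gridValues(g); bad[1] <- -2
  writeLines(c("dosiomics-grid 1", "type dose", "dims 1 1 2",
               "spacing 1 1 1", "origin 0 0 0", "-2 1"),
             file.path(tempdir(), "neg.dgrid"))
  expect_error(readVolume(file.path(tempdir(), "neg.dgrid")), ">= 0")
})

test_that("resampling is identity at target spacing and exact on constants", {
  g <- randomGrid(c(5, 5, 5))
  expect_identical(resampleToIso(g, c(1.5, 1.5, 1.5)), g)  # bitwise no-op
  cg <- uniformGrid(7, dims = c(4, 4, 4), spacing = c(3, 3, 3))
  r <- resampleToIso(cg)
  expect_equal(gridSpacing(r), c(1.5, 1.5, 1.5))
  expect_true(all(gridValues(r) == 7))
  # physical extent preserved to within one source voxel per axis
  expect_true(all(abs(gridDim(r) * gridSpacing(r) -
                      gridDim(cg) * gridSpacing(cg)) <= gridSpacing(cg)))
  expect_error(resampleToIso(g, c(0, 1, 1)), "positive")
})

test_that("trilinear resampling halves a coarse ramp exactly", {
  n <- 8
  ramp <- aperm(array(rep(seq(0, 21, by = 3), each = 16), c(4, 4, n)),
                c(3, 1, 2))
  g <- DoseGrid(ramp, spacing = c(3, 1.5, 1.5))
  r <- resampleToIso(g)
  v <- gridValues(r)
  expect_equal(dim(v)[1], 16L)
  # even output samples coincide with input samples; odd ones are midpoints
  expect_equal(v[seq(1, 15, by = 2), 1, 1], seq(0, 21, by = 3))
  expect_equal(v[seq(2, 14, by = 2), 1, 1],
               (seq(0, 18, by = 3) + seq(3, 21, by = 3)) / 2)
  expect_equal(v[16, 1, 1], 21)  # clamped endpoint preserved
})

test_that("mask resampling stays binary", {
  set.seed(3)
  for (i in 1:5) {
    m <- randomMask(c(5, 4, 6), p = 0.5, spacing = c(2, 3, 2.5))
    r <- resampleToIso(m)
    expect_true(all(gridValues(r) %in% c(0, 1)))
    expect_s4_class(r, "RoiMask")
  }
})

test_that("fraction summation is linear, order-free and geometry-checked", {
  f <- replicate(5, uniformGrid(2, dims = c(3, 3, 3)))
  s <- sumFractions(FractionSeries("p", f))
  expect_true(all(gridValues(s) == 10))
  one <- randomGrid(c(3, 3, 3))
  expect_equal(gridValues(sumFractions(FractionSeries("p", list(one)))),
               gridValues(one))
  zero <- uniformGrid(0, c(3, 3, 3))
  expect_equal(gridValues(sumFractions(FractionSeries("p", list(one, zero)))),
               gridValues(one))
  set.seed(4)
  fr <- replicate(4, randomGrid(c(3, 3, 3)), simplify = FALSE)
  a <- sumFractions(FractionSeries("p", fr))
  b <- sumFractions(FractionSeries("p", rev(fr)))
  expect_equal(gridValues(a), gridValues(b), tolerance = 1e-12)
  scaled <- lapply(fr, function(g) DoseGrid(gridValues(g) * 3, gridSpacing(g)))
  expect_equal(gridValues(sumFractions(FractionSeries("p", scaled))),
               gridValues(a) * 3, tolerance = 1e-12)
  mismatched <- list(uniformGrid(1, c(3, 3, 3)), uniformGrid(1, c(4, 3, 3)))
  expect_error(FractionSeries("p", mismatched), "harmonize")
})

test_that("harmonizeSeries resamples mismatched fractions to the first grid", {
  a <- uniformGrid(2, dims = c(4, 4, 4), spacing = c(3, 3, 3))
  b <- uniformGrid(1, dims = c(8, 8, 8), spacing = c(1.5, 1.5, 1.5))
  s <- harmonizeSeries("p", list(a, b))
  expect_equal(nFractions(s), 2L)
  expect_equal(gridDim(fractions(s)[[2]]), c(4L, 4L, 4L))
  expect_true(all(gridValues(fractions(s)[[2]]) == 1))
})
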