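# Shared fixture builders (all generated in code; no stored data).

uniformGrid <- function(value, dims = c(4, 4, 4), spacing = c(1.5, 1.5, 1.5)) {
  DoseGrid(array(value, dims), spacing = spacing)
}

fullMask <- function(dims = c(4, 4, 4), spacing = c(1.5, 1.5, 1.5)) {
  RoiMask(array(1, dims), spacing = spacing)
}

randomGrid <- function(dims, lo = 0, hi = 60, spacing = c(1.5, 1.5, 1.5)) {
  DoseGrid(array(runif(prod(dims), lo, hi), dims), spacing = spacing)
}

randomMask <- function(dims, p = 0.7, spacing = c(1.5, 1.5, 1.5)) {
  repeat {
    v <- array(rbinom(prod(dims), 1, p), dims)
    if (sum(v) >= 2) return(RoiMask(v, spacing = spacing))
  }
}

# Quantized volume straight from an integer level array (0 = outside mask).
quantizedFrom <- function(levels) {
  dims <- dim(levels)
  g <- DoseGrid(array(pmax(levels - 0.5, 0), dims))
  m <- RoiMask(array(as.numeric(levels > 0), dims))
  discretizeDose(g, m, discretizationSpec(binWidth = 1, maxLevels = 200))
}

# A small logistic dataset with one informative feature and noise features.
logisticToy <- function(n = 80, pNoise = 4, beta = 3, seed = 42) {
  set.seed(seed)
  x <- matrix(runif(n * (pNoise + 1)), nrow = n, ncol = pNoise + 1)
  colnames(x) <- c("signal", if (pNoise > 0) paste0("noise", seq_len(pNoise)))
  y <- rbinom(n, 1, plogis(-beta / 2 + beta * x[, 1]))
  list(X = x, y = y)
}

# A hand-built cohort (bypassing the generator) whose fractions are all
# uniform 2 Gy: the EQD2 fixed point.
twoGyCohort <- function(nPatients = 6, nFrac = 5, dims = c(10, 10, 10)) {
  mask <- RoiMask(array(rep(c(1, 1, 1, 0), length.out = prod(dims)), dims),
                  spacing = c(6, 6, 6))
  patients <- lapply(seq_len(nPatients), function(i) {
    fr <- replicate(nFrac,
                    DoseGrid(array(2, dims), spacing = c(6, 6, 6)))
    list(series = FractionSeries(sprintf("T%02d", i), fr), mask = mask)
  })
  table <- data.frame(patientId = sprintf("T%02d", seq_len(nPatients)),
                      label = rep(c(0L, 1L), length.out = nPatients))
  list(patients = patients, table = table)
}

# Fabricate a GroupResult with given per-split AUCs (for evaluation tests).
fakeGroupResult <- function(aucs, tag = "DVH", scores = NULL, labels = NULL) {
  splits <- lapply(seq_along(aucs), function(k) {
    list(split = k, seed = k, trainIdx = 1:4, testIdx = 5:8, redraws = 0L,
         bounds = rbind(min = c(f1 = 0), max = c(f1 = 1)),
         chosenC = 1, intercept = 0,
         coefficients = c(f1 = log(2)), selected = "f1",
         testScores = if (is.null(scores)) rep(0, 4) else scores[[k]],
         testLabels = if (is.null(labels)) c(0, 1, 0, 1) else labels[[k]],
         testAUC = aucs[k])
  })
  new("GroupResult", groupTag = tag, featureNames = "f1",
      labels = c(0L, 1L, 0L, 1L), splits = splits,
      config = unclass(deskModelingConfig(nSplits = length(aucs))))
}
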