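## Dosiomic feature extraction: fixed-bin discretization, 18 first-order
## statistics and 75 texture features over five matrix families
## (GLCM 24, GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14). Matrix accumulation is
## done in C++ (src/texture.cpp); all feature formulas are restated in the
## methods vignette so the implementation is self-contained.
##
## Degenerate-denominator conventions: features whose denominator vanishes on
## (near-)constant volumes (GLCM correlation and MCC, NGTDM coarseness,
## busyness and strength, first-order skewness/kurtosis) return 0 with a
## warning, so constant inputs yield deterministic finite vectors.

#' Discretization specification for texture analysis
#'
#' Fixed-width dose bins anchored at `origin` (default 0 Gy, so level k spans
#' `[k-1, k)` Gy), clamped to at most `maxLevels` levels.
#'
#' @param binWidth bin width in Gy (> 0), default 1.
#' @param maxLevels maximum number of gray levels (>= 2), default 100.
#' @param origin bin anchor in Gy, default 0.
#' @return A named list of class `DiscretizationSpec`.
#' @export
discretizationSpec <- function(binWidth = 1, maxLevels = 100L, origin = 0) {
  if (binWidth <= 0) stop("bin width must be > 0")
  if (maxLevels < 2) stop("need at least 2 levels")
  structure(list(binWidth = binWidth, maxLevels = as.integer(maxLevels),
                 origin = origin), class = "DiscretizationSpec")
}

#' Discretize a dose grid over a mask
#'
#' In-mask voxels get level `floor((dose - origin)/binWidth) + 1`, clamped to
#' `[1, maxLevels]` (a warning reports clamping); out-of-mask voxels get 0
#' and are excluded from all matrix accumulations.
#'
#' @param dose a [DoseGrid-class].
#' @param mask an aligned [RoiMask-class].
#' @param spec a [discretizationSpec()].
#' @return A [QuantizedVolume-class].
#' @export
discretizeDose <- function(dose, mask, spec = discretizationSpec()) {
  .checkAligned(dose, mask)
  inMask <- mask@values > 0.5
  if (!any(inMask)) stop("empty mask")
  lv <- array(0L, dim(dose@values))
  raw <- floor((dose@values[inMask] - spec$origin) / spec$binWidth) + 1
  if (any(raw > spec$maxLevels))
    warning(sprintf("%d voxel(s) above the top dose bin were clamped to level %d",
                    sum(raw > spec$maxLevels), spec$maxLevels))
  lv[inMask] <- as.integer(pmin(pmax(raw, 1), spec$maxLevels))
  new("QuantizedVolume", levels = lv, ng = max(lv),
      binWidth = spec$binWidth, binOrigin = spec$origin,
      voxelVolume = prod(dose@spacing))
}

.degenerate0 <- function(what) {
  warning("degenerate denominator in ", what, "; returning 0", call. = FALSE)
  0
}

## ---- first order ------------------------------------------------------------

#' First-order dose statistics (18 features)
#'
#' Computed over the continuous in-mask dose, except entropy and uniformity,
#' which use the fixed-bin discretized histogram. Percentiles use linear
#' interpolation between order statistics. Skewness and kurtosis (non-excess,
#' `m4/m2^2`) of a constant volume are returned as 0.
#'
#' @inheritParams discretizeDose
#' @return Named numeric vector of 18 `firstorder_*` features.
#' @export
firstOrderFeatures <- function(dose, mask, spec = discretizationSpec()) {
  x <- .maskedDoses(dose, mask)
  n <- length(x)
  q <- discretizeDose(dose, mask, spec)
  p <- tabulate(q@levels[q@levels > 0L], nbins = q@ng)
  p <- p[p > 0] / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p10 <- unname(quantile(x, 0.10, type = 7))
  p90 <- unname(quantile(x, 0.90, type = 7))
  mid <- x[x >= p10 & x <= p90]
  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = prod(dose@spacing) * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_Percentile10 = p10,
    firstorder_Percentile90 = p90,
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = median(x),
    firstorder_InterquartileRange =
      unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

## ---- GLCM -------------------------------------------------------------------

.glcmFeatureOne <- function(P) {
  # P: symmetric normalized co-occurrence matrix for one direction
  ng <- nrow(P)
  i <- seq_len(ng)
  I <- matrix(i, ng, ng)
  J <- t(I)
  px <- rowSums(P)                       # == py by symmetry
  mux <- sum(i * px)
  sx2 <- sum((i - mux)^2 * px)
  # diagonal-band distributions
  ksum <- 2:(2 * ng)
  psum <- vapply(ksum, function(k) sum(P[I + J == k]), numeric(1))
  kdiff <- 0:(ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(P[abs(I - J) == k]), numeric(1))
  nz <- P > 0
  hxy <- -sum(P[nz] * log2(P[nz]))
  pxpy <- outer(px, px)
  ok <- nz & pxpy > 0
  hxy1 <- -sum(P[ok] * log2(pxpy[ok]))
  okm <- pxpy > 0
  hxy2 <- -sum(pxpy[okm] * log2(pxpy[okm]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  da <- sum(kdiff * pdiff)
  occ <- which(px > 0)
  corr <- if (sx2 > 0) (sum(I * J * P) - mux^2) / sx2 else
    .degenerate0("GLCM correlation")
  mcc <- if (length(occ) < 2) .degenerate0("GLCM MCC") else {
    Q <- matrix(0, length(occ), length(occ))
    Psub <- P[occ, occ, drop = FALSE]
    pxo <- px[occ]
    for (a in seq_along(occ))
      Q[a, ] <- colSums(t(Psub) * Psub[a, ] / pxo) / pxo[a]
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(glcm_Autocorrelation = sum(I * J * P),
    glcm_ClusterProminence = sum((I + J - 2 * mux)^4 * P),
    glcm_ClusterShade = sum((I + J - 2 * mux)^3 * P),
    glcm_ClusterTendency = sum((I + J - 2 * mux)^2 * P),
    glcm_Contrast = sum((I - J)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0])),
    glcm_DifferenceVariance = sum((kdiff - da)^2 * pdiff),
    glcm_Id = sum(pdiff / (1 + kdiff)),
    glcm_Idm = sum(pdiff / (1 + kdiff^2)),
    glcm_Idmn = sum(pdiff / (1 + kdiff^2 / ng^2)),
    glcm_Idn = sum(pdiff / (1 + kdiff / ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(pdiff[-1] / kdiff[-1]^2),
    glcm_JointAverage = mux,
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = hxy,
    glcm_MaximumProbability = max(P),
    glcm_MCC = mcc,
    glcm_SumAverage = sum(ksum * psum),
    glcm_SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    glcm_SumSquares = sx2)
}

#' Gray-level co-occurrence features (24)
#'
#' Symmetrized co-occurrence matrices over the 13 unique 3D offsets at
#' Chebyshev distance 1; each direction's matrix is normalized, features are
#' computed per direction and averaged.
#'
#' @param q a [QuantizedVolume-class] from [discretizeDose()].
#' @return Named numeric vector of 24 `glcm_*` features.
#' @export
glcmFeatures <- function(q) {
  counts <- .cppGlcmCounts(as.integer(q@levels), dim(q@levels), q@ng)
  perDir <- apply(counts, 3, function(m) {
    tot <- sum(m)
    if (tot == 0) stop("no voxel pairs: mask too small for GLCM")
    .glcmFeatureOne(matrix(m / tot, q@ng, q@ng))
  })
  rowMeans(perDir)
}

## ---- GLRLM ------------------------------------------------------------------

.rlmFeatureOne <- function(P, np, prefix, jname) {
  # P: levels x sizes count matrix; np: voxel count
  i <- seq_len(nrow(P))
  j <- seq_len(ncol(P))
  Ns <- sum(P)
  pg <- rowSums(P)
  ps <- colSums(P)
  pn <- P / Ns
  mui <- sum(i * rowSums(pn))
  muj <- sum(j * colSums(pn))
  ent <- -sum(pn[pn > 0] * log2(pn[pn > 0]))
  Wi2 <- matrix(i^2, nrow(P), ncol(P))
  Wj2 <- matrix(j^2, nrow(P), ncol(P), byrow = TRUE)
  f <- c(sum(P / Wj2) / Ns,                 # short emphasis
         sum(P * Wj2) / Ns,                 # long emphasis
         sum(pg^2) / Ns,                    # GLN
         sum(pg^2) / Ns^2,                  # GLNN
         sum(ps^2) / Ns,                    # size NU
         sum(ps^2) / Ns^2,                  # size NUN
         Ns / np,                           # percentage
         sum(pn * (matrix(i, nrow(P), ncol(P)) - mui)^2),   # GL variance
         sum(pn * (matrix(j, nrow(P), ncol(P), byrow = TRUE) - muj)^2),
         ent,
         sum(P / Wi2) / Ns,                 # low GL emphasis
         sum(P * Wi2) / Ns,                 # high GL emphasis
         sum(P / (Wi2 * Wj2)) / Ns,         # short+low
         sum(P * Wi2 / Wj2) / Ns,           # short+high
         sum(P * Wj2 / Wi2) / Ns,           # long+low
         sum(P * Wi2 * Wj2) / Ns)           # long+high
  names(f) <- paste0(prefix, c(
    paste0("Short", jname, "Emphasis"), paste0("Long", jname, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(jname, "LengthNonUniformity"),
    paste0(jname, "LengthNonUniformityNormalized"),
    paste0(jname, "Percentage"), "GrayLevelVariance",
    paste0(jname, "Variance"), paste0(jname, "Entropy"),
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    paste0("Short", jname, "LowGrayLevelEmphasis"),
    paste0("Short", jname, "HighGrayLevelEmphasis"),
    paste0("Long", jname, "LowGrayLevelEmphasis"),
    paste0("Long", jname, "HighGrayLevelEmphasis")))
  f
}

#' Gray-level run-length features (16)
#'
#' Maximal constant-level runs along each of the 13 unique 3D directions
#' (out-of-mask voxels break runs); features are computed per direction and
#' averaged.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of 16 `glrlm_*` features.
#' @export
glrlmFeatures <- function(q) {
  counts <- .cppGlrlmCounts(as.integer(q@levels), dim(q@levels), q@ng)
  np <- sum(q@levels > 0L)
  perDir <- apply(counts, 3, function(m) {
    m <- matrix(m, q@ng)
    .rlmFeatureOne(m, np, "glrlm_", "Run")
  })
  rowMeans(perDir)
}

## ---- GLSZM ------------------------------------------------------------------

#' Gray-level size-zone features (16)
#'
#' Zones are 26-connected components of constant level within the mask; a
#' single levels x zone-size matrix is built (no direction dependence).
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of 16 `glszm_*` features.
#' @export
glszmFeatures <- function(q) {
  zones <- .cppGlszmZones(as.integer(q@levels), dim(q@levels))
  np <- sum(q@levels > 0L)
  smax <- max(zones[, 2])
  P <- matrix(0, q@ng, smax)
  for (k in seq_len(nrow(zones)))
    P[zones[k, 1], zones[k, 2]] <- P[zones[k, 1], zones[k, 2]] + 1
  f <- .rlmFeatureOne(P, np, "glszm_", "Zone")
  # zone-family naming deviates from the run-length template in three places
  names(f) <- c("glszm_SmallAreaEmphasis", "glszm_LargeAreaEmphasis",
                "glszm_GrayLevelNonUniformity",
                "glszm_GrayLevelNonUniformityNormalized",
                "glszm_SizeZoneNonUniformity",
                "glszm_SizeZoneNonUniformityNormalized",
                "glszm_ZonePercentage", "glszm_GrayLevelVariance",
                "glszm_ZoneVariance", "glszm_ZoneEntropy",
                "glszm_LowGrayLevelZoneEmphasis",
                "glszm_HighGrayLevelZoneEmphasis",
                "glszm_SmallAreaLowGrayLevelEmphasis",
                "glszm_SmallAreaHighGrayLevelEmphasis",
                "glszm_LargeAreaLowGrayLevelEmphasis",
                "glszm_LargeAreaHighGrayLevelEmphasis")
  f
}

## ---- NGTDM ------------------------------------------------------------------

#' Neighborhood gray-tone difference features (5)
#'
#' For each occupied level i, `n_i` counts in-mask voxels of level i having
#' at least one in-mask 26-neighbour and `s_i` sums `|i - mean level of the
#' in-mask 26-neighbourhood|` over those voxels. Busyness, coarseness and
#' strength of a single-level volume are 0 by the degenerate-denominator
#' convention.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of 5 `ngtdm_*` features.
#' @export
ngtdmFeatures <- function(q) {
  m <- .cppNgtdm(as.integer(q@levels), dim(q@levels), q@ng)
  n <- m[, 1]
  s <- m[, 2]
  nv <- sum(n)
  if (nv == 0) stop("no voxel has an in-mask neighbour; mask too small")
  p <- n / nv
  occ <- which(p > 0)
  ngp <- length(occ)
  io <- occ
  po <- p[occ]
  so <- s[occ]
  coarsenessDen <- sum(po * so)
  coarseness <- if (coarsenessDen > 0) 1 / coarsenessDen else
    .degenerate0("NGTDM coarseness")
  contrast <- if (ngp > 1)
    (sum(outer(po, po) * outer(io, io, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(so) / nv)
  else 0
  busyDen <- sum(abs(outer(io * po, io * po, `-`)))
  busyness <- if (busyDen > 0) sum(po * so) / busyDen else
    .degenerate0("NGTDM busyness")
  complexity <- sum(abs(outer(io, io, `-`)) *
                    (outer(po * so, po * so, `+`)) / outer(po, po, `+`)) / nv
  strengthDen <- sum(so)
  strength <- if (strengthDen > 0)
    sum(outer(po, po, `+`) * outer(io, io, `-`)^2) / strengthDen
  else .degenerate0("NGTDM strength")
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

## ---- GLDM -------------------------------------------------------------------

#' Gray-level dependence features (14)
#'
#' The dependence of a voxel is the number of its in-mask 26-neighbours whose
#' level differs by at most `alpha`. Counts are stored by neighbour count
#' d = 0..26; feature formulas weight by dependence size j = d + 1 (the voxel
#' itself is counted), so the small/large-dependence ratios stay finite.
#'
#' @inheritParams glcmFeatures
#' @param alpha dependence tolerance on level difference (default 0).
#' @return Named numeric vector of 14 `gldm_*` features.
#' @export
gldmFeatures <- function(q, alpha = 0L) {
  C <- .cppGldmCounts(as.integer(q@levels), dim(q@levels), q@ng,
                      as.integer(alpha))
  i <- seq_len(nrow(C))
  j <- seq_len(ncol(C))        # dependence size = neighbour count + 1
  Nz <- sum(C)
  pn <- C / Nz
  pg <- rowSums(C)
  pd <- colSums(C)
  mui <- sum(i * rowSums(pn))
  muj <- sum(j * colSums(pn))
  Wi2 <- matrix(i^2, nrow(C), ncol(C))
  Wj2 <- matrix(j^2, nrow(C), ncol(C), byrow = TRUE)
  c(gldm_SmallDependenceEmphasis = sum(C / Wj2) / Nz,
    gldm_LargeDependenceEmphasis = sum(C * Wj2) / Nz,
    gldm_GrayLevelNonUniformity = sum(pg^2) / Nz,
    gldm_DependenceNonUniformity = sum(pd^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(pd^2) / Nz^2,
    gldm_GrayLevelVariance = sum(pn * (matrix(i, nrow(C), ncol(C)) - mui)^2),
    gldm_DependenceVariance =
      sum(pn * (matrix(j, nrow(C), ncol(C), byrow = TRUE) - muj)^2),
    gldm_DependenceEntropy = -sum(pn[pn > 0] * log2(pn[pn > 0])),
    gldm_LowGrayLevelEmphasis = sum(C / Wi2) / Nz,
    gldm_HighGrayLevelEmphasis = sum(C * Wi2) / Nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(C / (Wi2 * Wj2)) / Nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(C * Wi2 / Wj2) / Nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(C * Wj2 / Wi2) / Nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(C * Wi2 * Wj2) / Nz)
}

## ---- all dosiomic features --------------------------------------------------

#' Extract the full dosiomic feature vector (93 features)
#'
#' Concatenates, in fixed canonical order, 18 first-order + 24 GLCM +
#' 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM features.
#'
#' @inheritParams discretizeDose
#' @param gldmAlpha GLDM dependence tolerance (default 0).
#' @return Named numeric vector of 93 features.
#' @export
extractDosiomicFeatures <- function(dose, mask, spec = discretizationSpec(),
                                    gldmAlpha = 0L) {
  q <- discretizeDose(dose, mask, spec)
  c(firstOrderFeatures(dose, mask, spec),
    glcmFeatures(q),
    glrlmFeatures(q),
    glszmFeatures(q),
    ngtdmFeatures(q),
    gldmFeatures(q, gldmAlpha))
}

#' Canonical dosiomic feature names
#'
#' @return Character vector of the 93 feature names in extraction order.
#' @export
dosiomicFeatureNames <- function() {
  g <- DoseGrid(array(rep(c(1, 2.2, 3.4, 0.3), 8), c(4, 4, 2)))
  m <- RoiMask(array(1, c(4, 4, 2)))
  names(suppressWarnings(extractDosiomicFeatures(g, m)))
}
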