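## Dose-volume-histogram features over the lung ROI.

#' DVH feature specification
#'
#' @param vxThresholds Vx thresholds in Gy; default `seq(5, 70, by = 5)`
#'   (V5..V70), strictly increasing and positive.
#' @param geudN gEUD volume-effect parameter n in (0, 1]; default 0.99
#'   (near-parallel lung).
#' @param strictInequality if `TRUE`, Vx counts voxels with dose strictly
#'   greater than x; the default `FALSE` uses the conventional `>= x`
#'   cumulative-DVH rule (the two differ only on exact ties).
#' @return A named list of class `DvhSpec`.
#' @export
dvhSpec <- function(vxThresholds = seq(5, 70, by = 5), geudN = 0.99,
                    strictInequality = FALSE) {
  if (any(vxThresholds <= 0) || is.unsorted(vxThresholds, strictly = TRUE))
    stop("Vx thresholds must be strictly increasing and > 0")
  if (geudN <= 0 || geudN > 1) stop("gEUD n must be in (0, 1]")
  structure(list(vxThresholds = vxThresholds, geudN = geudN,
                 strictInequality = strictInequality), class = "DvhSpec")
}

#' Relative lung volume receiving at least x Gy (Vx)
#'
#' @param dose a [DoseGrid-class].
#' @param mask an aligned [RoiMask-class].
#' @param x dose threshold in Gy.
#' @param strict use strictly-greater instead of the default `>=`.
#' @return Fraction of masked voxels at or above `x`, in `[0, 1]` (conversion
#'   to percent is left to the reporting layer).
#' @export
relativeVolumeAbove <- function(dose, mask, x, strict = FALSE) {
  d <- .maskedDoses(dose, mask)
  if (strict) mean(d > x) else mean(d >= x)
}

#' Mean lung dose (MLD)
#'
#' @inheritParams relativeVolumeAbove
#' @return Arithmetic mean of dose over masked voxels, in Gy.
#' @export
meanLungDose <- function(dose, mask) mean(.maskedDoses(dose, mask))

#' Generalized equivalent uniform dose (gEUD)
#'
#' Computed in the volume-averaged form
#' `((1/N) * sum_i D_i^(1/n))^n` over the N masked voxels, which is
#' scale-invariant in voxel count and reduces exactly to the mean lung dose
#' at n = 1. The literal unnormalized power sum `(sum_i D_i^(1/n))^n` is
#' available behind `literal = TRUE` for audit; it is not used by the
#' pipeline.
#'
#' @inheritParams relativeVolumeAbove
#' @param n volume-effect parameter in (0, 1].
#' @param literal use the unnormalized power-sum form.
#' @return gEUD in Gy.
#' @export
geud <- function(dose, mask, n = 0.99, literal = FALSE) {
  if (n <= 0 || n > 1) stop("gEUD n must be in (0, 1]")
  d <- .maskedDoses(dose, mask)
  s <- sum(d^(1 / n))
  if (!literal) s <- s / length(d)
  s^n
}

#' Extract the DVH feature vector
#'
#' Emits, in deterministic order, V5..V70 (as fractions), MLD and gEUD.
#'
#' @inheritParams relativeVolumeAbove
#' @param spec a [dvhSpec()].
#' @return Named numeric vector (default spec: 14 Vx + MLD + gEUD = 16
#'   features).
#' @export
extractDvhFeatures <- function(dose, mask, spec = dvhSpec()) {
  d <- .maskedDoses(dose, mask)
  vx <- vapply(spec$vxThresholds,
               function(x) if (spec$strictInequality) mean(d > x)
                           else mean(d >= x),
               numeric(1))
  names(vx) <- paste0("V", spec$vxThresholds)
  c(vx,
    MLD = mean(d),
    gEUD = (sum(d^(1 / spec$geudN)) / length(d))^spec$geudN)
}
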