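## Linear-quadratic EQD2 conversion.
##
## The equivalent dose in 2 Gy fractions accumulated over fractions i with
## per-voxel fraction dose d_i is
##   EQD2 = sum_i (d_i + d_i^2 / (a/b)) / (1 + 2 / (a/b)),
## applied voxel-wise. The correction is accumulated fraction by fraction,
## never from the summed physical dose: whenever the per-voxel fraction size
## varies across fractions (e.g. different beam arrangements per fraction)
## the two differ, which is exactly the effect the pipeline quantifies.

#' Linear-quadratic model parameters
#'
#' @param alphaBeta tissue alpha/beta ratio in Gy; must be > 0. Default 3 Gy,
#'   the value conventionally assumed for late lung toxicity.
#' @param referenceFractionDose reference fraction size in Gy (fixed at 2 for
#'   EQD2).
#' @return A named list of class `LqParams`.
#' @export
lqParams <- function(alphaBeta = 3, referenceFractionDose = 2) {
  if (!is.finite(alphaBeta) || alphaBeta <= 0)
    stop("alpha/beta must be a positive number")
  structure(list(alphaBeta = alphaBeta,
                 referenceFractionDose = referenceFractionDose),
            class = "LqParams")
}

#' EQD2 of a single fraction dose
#'
#' @param d dose per fraction in Gy (scalar or vector), all >= 0.
#' @param params an [lqParams()] object.
#' @return `(d + d^2/(a/b)) / (1 + 2/(a/b))` in Gy. `d = 2` Gy is the fixed
#'   point; smaller fraction doses are down-weighted, larger ones up-weighted.
#' @examples
#' eqd2Scalar(3, lqParams(alphaBeta = 3))   # 3.6
#' @export
eqd2Scalar <- function(d, params = lqParams()) {
  if (any(d < 0)) stop("fraction dose must be >= 0")
  ab <- params$alphaBeta
  r <- params$referenceFractionDose
  (d + d^2 / ab) / (1 + r / ab)
}

#' Accumulate a fraction series to an EQD2 grid
#'
#' Applies the per-fraction EQD2 correction voxel-wise and sums over
#' fractions.
#'
#' @param series a harmonized [FractionSeries-class].
#' @param params an [lqParams()] object.
#' @return A [DoseGrid-class] of accumulated EQD2 (Gy).
#' @export
eqd2Accumulate <- function(series, params = lqParams()) {
  stopifnot(is(series, "FractionSeries"))
  fr <- series@fractions
  acc <- eqd2Scalar(fr[[1L]]@values, params)
  if (length(fr) > 1L)
    for (g in fr[-1L]) acc <- acc + eqd2Scalar(g@values, params)
  DoseGrid(acc, fr[[1L]]@spacing, fr[[1L]]@origin, fr[[1L]]@orientation)
}
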