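## Resampling to the analysis grid and physical dose accumulation.

#' Resample a grid to isotropic spacing
#'
#' Dose grids are interpolated trilinearly; masks use nearest-neighbour
#' interpolation (so values stay binary). The output keeps the input origin;
#' the voxel count per axis is `round(n * spacing / target)`, which preserves
#' the physical extent to within one source voxel. A grid already at the
#' target spacing is returned unchanged.
#'
#' @param grid a [DoseGrid-class] or [RoiMask-class].
#' @param targetSpacing numeric(3) in mm; default `c(1.5, 1.5, 1.5)`, the
#'   analysis resolution used throughout the pipeline.
#' @return An object of the same class as `grid` at the target spacing.
#' @examples
#' g <- DoseGrid(array(runif(4^3), c(4, 4, 4)), spacing = c(3, 3, 3))
#' gridDim(resampleToIso(g))      # 8 x 8 x 8 at 1.5 mm
#' @export
resampleToIso <- function(grid, targetSpacing = c(1.5, 1.5, 1.5)) {
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) != 3L || any(!is.finite(targetSpacing)) ||
      any(targetSpacing <= 0))
    stop("target spacing must be 3 strictly positive values")
  if (all(.relDiff(grid@spacing, targetSpacing) <= .GEOM_TOL))
    return(grid)
  d <- dim(grid@values)
  newDims <- pmax(1L, as.integer(round(d * grid@spacing / targetSpacing)))
  isMask <- is(grid, "RoiMask")
  vals <- .cppResample(as.numeric(grid@values), as.integer(d), grid@spacing,
                       newDims, targetSpacing, isMask)
  if (isMask)
    RoiMask(vals, targetSpacing, grid@origin, grid@orientation)
  else
    DoseGrid(vals, targetSpacing, grid@origin, grid@orientation)
}

#' Harmonize a fraction series onto a common geometry
#'
#' Fractions delivered on mismatched grids are resampled (trilinearly) to the
#' first fraction's geometry before any accumulation.
#'
#' @param patientId patient identifier.
#' @param fractions list of [DoseGrid-class] objects, possibly on different
#'   grids (must share origin and axis order; spacing/shape may differ).
#' @return A valid [FractionSeries-class].
#' @export
harmonizeSeries <- function(patientId, fractions) {
  stopifnot(length(fractions) >= 1L)
  ref <- fractions[[1L]]
  fr <- lapply(fractions, function(g) {
    if (.sameGeometry(ref, g)) return(g)
    if (any(.relDiff(g@origin, ref@origin) > .GEOM_TOL))
      stop("fractions have different origins; cannot harmonize")
    out <- resampleToIso(g, ref@spacing)
    if (!identical(dim(out@values), dim(ref@values)))
      stop("fraction grids could not be harmonized to a common shape")
    out
  })
  FractionSeries(patientId, fr)
}

#' Voxel-wise sum of all fractions (uncorrected physical dose)
#'
#' @param series a harmonized [FractionSeries-class].
#' @return A [DoseGrid-class] holding the plain voxel-wise sum.
#' @seealso [eqd2Accumulate()] for the fraction-size-corrected accumulation.
#' @export
sumFractions <- function(series) {
  stopifnot(is(series, "FractionSeries"))
  fr <- series@fractions
  total <- fr[[1L]]@values
  if (length(fr) > 1L)
    for (g in fr[-1L]) total <- total + g@values
  DoseGrid(total, fr[[1L]]@spacing, fr[[1L]]@origin, fr[[1L]]@orientation)
}
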