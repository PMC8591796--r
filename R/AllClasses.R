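#' @import methods
#' @importFrom stats quantile cor rnorm runif rbinom sd median plogis pnorm
#'   uniroot approx rgamma chisq.test fft setNames
#' @importFrom utils head read.csv write.csv
#' @useDynLib dosiomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.GEOM_TOL <- 1e-6

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Volumetric grid classes
#'
#' `DoseGrid` holds one 3D absorbed-dose field (Gy) on a regular grid;
#' `RoiMask` holds a binary region-of-interest mask on the same kind of grid.
#' Internally arrays are indexed (x, y, z) and the world coordinate of voxel
#' (i, j, k) is `origin + (c(i, j, k) - 1) * spacing` (mm).
#'
#' @slot values 3D numeric array; dose in Gy, or 0/1 for masks.
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#' @slot origin numeric(3), world coordinate of the first voxel centre (mm).
#' @slot orientation single string tagging the source orientation convention.
#'
#' @name DoseGrid-class
#' @aliases RoiMask-class
#' @exportClass DoseGrid
setClass("DoseGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 orientation = "character"),
  prototype(orientation = "internal-xyz"))

setValidity("DoseGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("expected 3 axes")
  if (any(dim(v) < 1L)) return("every axis must have length >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  if (any(!is.finite(v))) return("dose values must all be finite")
  if (any(v < 0)) return("dose values must be >= 0")
  TRUE
})

#' @exportClass RoiMask
setClass("RoiMask", contains = "DoseGrid")

setValidity("RoiMask", function(object) {
  v <- object@values
  if (!all(v %in% c(0, 1))) return("mask values must be 0 or 1")
  if (sum(v) < 1) return("mask must contain at least one foreground voxel")
  TRUE
})

#' Ordered per-fraction dose grids for one patient
#'
#' All fractions must share shape, spacing and origin (to within 1e-6
#' relative); use [harmonizeSeries()] first when they do not.
#'
#' @slot patientId single string.
#' @slot fractions list of [DoseGrid-class] objects on identical geometry.
#' @exportClass FractionSeries
setClass("FractionSeries",
  representation(patientId = "character", fractions = "list"))

setValidity("FractionSeries", function(object) {
  if (length(object@patientId) != 1L) return("patientId must be one string")
  fr <- object@fractions
  if (length(fr) < 1L) return("need at least one fraction")
  if (!all(vapply(fr, is, logical(1), "DoseGrid")))
    return("all fractions must be DoseGrid objects")
  g1 <- fr[[1L]]
  for (g in fr[-1L]) {
    if (!.sameGeometry(g1, g))
      return("fractions do not share shape/spacing/origin; harmonize first")
  }
  TRUE
})

#' Discretized (quantized) volume for texture analysis
#'
#' @slot levels 3D integer array; 0 outside the mask, 1..maxLevels inside.
#' @slot ng highest occupied level (matrix dimension for texture families).
#' @slot binWidth,binOrigin discretization bin width and anchor (Gy).
#' @slot voxelVolume voxel volume in mm^3 (carried for bookkeeping).
#' @exportClass QuantizedVolume
setClass("QuantizedVolume",
  representation(levels = "array", ng = "integer", binWidth = "numeric",
                 binOrigin = "numeric", voxelVolume = "numeric"))

setValidity("QuantizedVolume", function(object) {
  lv <- object@levels
  if (length(dim(lv)) != 3L) return("expected 3 axes")
  if (any(lv < 0)) return("levels must be >= 0")
  if (sum(lv > 0) < 1) return("no in-mask voxels")
  if (max(lv) != object@ng) return("ng must equal the highest occupied level")
  TRUE
})

#' Patients-by-features table with binary outcome labels
#'
#' @slot values numeric matrix, patients in rows (rownames = patient IDs),
#'   named feature columns; no missing values.
#' @slot labels integer vector of binary radiation-pneumonitis outcomes
#'   (1 = RP grade >= 1, 0 = grade 0), one per patient.
#' @slot groupTag one of "DVH", "DVHEQD2", "DO", "DOEQD2".
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", labels = "integer", groupTag = "character"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("feature columns must be uniquely named")
  if (any(!is.finite(v))) return("feature values must be finite (no missing)")
  if (length(object@labels) != nrow(v))
    return("one label per patient row required")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (min(table(factor(object@labels, levels = 0:1))) < 2L)
    return("need at least 2 patients in each outcome class")
  if (length(object@groupTag) != 1L ||
      !object@groupTag %in% c("DVH", "DVHEQD2", "DO", "DOEQD2"))
    return("groupTag must be one of DVH, DVHEQD2, DO, DOEQD2")
  TRUE
})

#' Result of repeated-holdout modeling for one feature group
#'
#' @slot groupTag the feature group modeled.
#' @slot featureNames column order of the modeled table.
#' @slot labels the binary outcome vector used.
#' @slot splits list of per-split results (see [runGroup()]).
#' @slot config the [modelingConfig()] list used.
#' @exportClass GroupResult
setClass("GroupResult",
  representation(groupTag = "character", featureNames = "character",
                 labels = "integer", splits = "list", config = "list"))

setValidity("GroupResult", function(object) {
  if (length(object@splits) < 1L) return("no splits")
  TRUE
})

## ---- constructors ----------------------------------------------------------

#' Construct a dose grid or ROI mask
#'
#' @param values 3D numeric array (dose in Gy; any value > 0.5 is foreground
#'   for `RoiMask`).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world coordinate of the first voxel centre (mm).
#' @param orientation orientation tag recorded by readers.
#' @return A [DoseGrid-class] or [RoiMask-class] object.
#' @examples
#' g <- DoseGrid(array(2, c(4, 4, 4)), spacing = c(1.5, 1.5, 1.5))
#' m <- RoiMask(array(1, c(4, 4, 4)), spacing = c(1.5, 1.5, 1.5))
#' @export
DoseGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     orientation = "internal-xyz") {
  if (length(dim(values)) != 3L) stop("expected 3 axes")
  new("DoseGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' @rdname DoseGrid
#' @export
RoiMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    orientation = "internal-xyz") {
  if (length(dim(values)) != 3L) stop("expected 3 axes")
  v <- array(as.numeric(values > 0.5), dim(values))
  new("RoiMask", values = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' Construct a per-fraction dose series
#'
#' @param patientId single string.
#' @param fractions list of [DoseGrid-class] objects on identical geometry.
#' @return A [FractionSeries-class] object.
#' @export
FractionSeries <- function(patientId, fractions) {
  new("FractionSeries", patientId = as.character(patientId),
      fractions = fractions)
}

#' Construct a feature table
#'
#' @param values patients x features numeric matrix with named columns.
#' @param labels binary outcome vector (1 = RP grade >= 1).
#' @param groupTag "DVH", "DVHEQD2", "DO" or "DOEQD2".
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(values, labels, groupTag) {
  new("FeatureTable", values = as.matrix(values),
      labels = as.integer(labels), groupTag = groupTag)
}

## ---- accessors -------------------------------------------------------------

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' Accessors for volumetric grids
#' @param x a [DoseGrid-class], [RoiMask-class] or [QuantizedVolume-class].
#' @return `gridValues`: the 3D array; `gridSpacing`/`gridOrigin`:
#'   numeric(3); `gridDim`: integer(3); `voxelVolume`: scalar mm^3.
#' @aliases gridValues gridSpacing gridOrigin gridDim voxelVolume
#' @name grid-accessors
#' @export
setMethod("gridValues", "DoseGrid", function(x) x@values)
setMethod("gridValues", "QuantizedVolume", function(x) x@levels)

#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
setMethod("gridSpacing", "DoseGrid", function(x) x@spacing)

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
setMethod("gridOrigin", "DoseGrid", function(x) x@origin)

#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
setMethod("gridDim", "DoseGrid", function(x) dim(x@values))
setMethod("gridDim", "QuantizedVolume", function(x) dim(x@levels))

#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
setMethod("voxelVolume", "DoseGrid", function(x) prod(x@spacing))

#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
setMethod("patientId", "FractionSeries", function(x) x@patientId)

#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' Accessors for fraction series
#' @param x a [FractionSeries-class].
#' @return `fractions`: list of [DoseGrid-class]; `nFractions`: integer;
#'   `patientId`: string.
#' @aliases fractions nFractions patientId
#' @name series-accessors
#' @export
setMethod("fractions", "FractionSeries", function(x) x@fractions)

#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))
setMethod("nFractions", "FractionSeries", function(x) length(x@fractions))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' Accessors for feature tables and group results
#' @param x a [FeatureTable-class] or [GroupResult-class].
#' @return `featureValues`: the numeric matrix; `rpLabels`: integer 0/1
#'   vector; `groupTag`: string; `featureNames`: character vector;
#'   `splitResults`: list of per-split results; `testAUCs`: numeric vector.
#' @aliases featureValues rpLabels groupTag featureNames splitResults testAUCs
#' @name table-accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @export
setGeneric("rpLabels", function(x) standardGeneric("rpLabels"))
setMethod("rpLabels", "FeatureTable", function(x) x@labels)
setMethod("rpLabels", "GroupResult", function(x) x@labels)

#' @export
setGeneric("groupTag", function(x) standardGeneric("groupTag"))
setMethod("groupTag", "FeatureTable", function(x) x@groupTag)
setMethod("groupTag", "GroupResult", function(x) x@groupTag)

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))
setMethod("featureNames", "GroupResult", function(x) x@featureNames)

#' @export
setGeneric("splitResults", function(x) standardGeneric("splitResults"))
setMethod("splitResults", "GroupResult", function(x) x@splits)

#' @export
setGeneric("testAUCs", function(x) standardGeneric("testAUCs"))
setMethod("testAUCs", "GroupResult",
          function(x) vapply(x@splits, `[[`, numeric(1), "testAUC"))

## ---- show ------------------------------------------------------------------

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %dx%dx%d, spacing (%g, %g, %g) mm, dose range [%g, %g] Gy\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@values), max(object@values)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiMask %dx%dx%d, spacing (%g, %g, %g) mm, %d foreground voxels\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], sum(object@values > 0)))
})

setMethod("show", "FractionSeries", function(object) {
  cat(sprintf("FractionSeries '%s': %d fractions of ", object@patientId,
              length(object@fractions)))
  show(object@fractions[[1L]])
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable [%s]: %d patients x %d features, %d/%d RP-positive\n",
              object@groupTag, nrow(object@values), ncol(object@values),
              sum(object@labels), length(object@labels)))
})

setMethod("show", "GroupResult", function(object) {
  aucs <- testAUCs(object)
  cat(sprintf("GroupResult [%s]: %d splits, mean test AUC %.3f (SD %.3f)\n",
              object@groupTag, length(object@splits), mean(aucs), sd(aucs)))
})

## ---- internal geometry helpers --------------------------------------------

.relDiff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1)

.sameGeometry <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    all(.relDiff(a@spacing, b@spacing) <= .GEOM_TOL) &&
    all(.relDiff(a@origin, b@origin) <= .GEOM_TOL)
}

.checkAligned <- function(dose, mask) {
  if (!.sameGeometry(dose, mask))
    stop("dose and mask geometry mismatch (shape/spacing/origin)")
  invisible(TRUE)
}

.maskedDoses <- function(dose, mask) {
  .checkAligned(dose, mask)
  dose@values[mask@values > 0.5]
}
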