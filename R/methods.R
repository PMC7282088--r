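#' @include AllClasses.R
NULL

## Accessors -----------------------------------------------------------------

#' Accessors for dwicadx data objects
#'
#' Small accessor generics used across the package: \code{s0Volume} and
#' \code{sHighVolume} return the raw signal arrays of a [DWISeries-class];
#' \code{adcValues} the array of an [ADCVolume-class]; \code{voxelSpacing}
#' the spacing in mm; \code{voiMask}, \code{coreMask} and \code{periMask}
#' the binary masks of the lesion model and sub-ROI objects.
#'
#' @param x a dwicadx object.
#' @param direction one of \code{"r"}, \code{"p"}, \code{"s"}.
#' @return The requested slot content (array, matrix or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("s0Volume", function(x) standardGeneric("s0Volume"))
#' @rdname accessors
#' @export
setMethod("s0Volume", "DWISeries", function(x) x@s0)

#' @rdname accessors
#' @export
setGeneric("sHighVolume", function(x, direction) standardGeneric("sHighVolume"))
#' @rdname accessors
#' @export
setMethod("sHighVolume", "DWISeries", function(x, direction) {
  direction <- match.arg(direction, DIRECTIONS)
  x@sHigh[[direction]]
})

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DWISeries", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ADCVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("adcValues", function(x) standardGeneric("adcValues"))
#' @rdname accessors
#' @export
setMethod("adcValues", "ADCVolume", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("voiMask", function(x) standardGeneric("voiMask"))
#' @rdname accessors
#' @export
setMethod("voiMask", "VOIMask3D", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("coreMask", function(x) standardGeneric("coreMask"))
#' @rdname accessors
#' @export
setMethod("coreMask", "SubROIPair", function(x) x@core)

#' @rdname accessors
#' @export
setGeneric("periMask", function(x) standardGeneric("periMask"))
#' @rdname accessors
#' @export
setMethod("periMask", "SubROIPair", function(x) x@peri)

#' @rdname accessors
#' @export
setGeneric("indexSlice", function(x) standardGeneric("indexSlice"))
#' @rdname accessors
#' @export
setMethod("indexSlice", "LesionAnnotation", function(x) x@indexSlice)

#' ROI mask of an annotation on one slice
#'
#' @param x a [LesionAnnotation-class].
#' @param slice slice index (1-based); defaults to the index slice.
#' @return Logical matrix.
#' @export
roiMask <- function(x, slice = indexSlice(x)) {
  m <- x@roiBySlice[[as.character(slice)]]
  if (is.null(m)) stop(sprintf("slice %s is not annotated", slice))
  m
}

#' AUC of an ROC fit
#' @param x a [ROCResult-class].
#' @param type \code{"fitted"} (binormal when available) or
#'   \code{"empirical"}.
#' @return Numeric AUC.
#' @export
aucValue <- function(x, type = c("fitted", "empirical")) {
  type <- match.arg(type)
  if (type == "fitted") x@auc else x@aucEmpirical
}

## show methods --------------------------------------------------------------

setMethod("show", "DWISeries", function(object) {
  d <- dim(object@s0)
  cat(sprintf("DWISeries '%s': %dx%dx%d voxels, spacing %.2fx%.2fx%.2f mm\n",
              object@lesionId, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  b=0 plus %d directional volumes at b=%g s/mm^2 (%s)\n",
              length(object@sHigh), object@bHigh,
              paste(names(object@sHigh), collapse = ", ")))
})

setMethod("show", "ADCVolume", function(object) {
  d <- dim(object@values)
  kind <- if (is(object, "AugmentedADCVolume")) "Augmented ADC" else "ADC"
  unit <- if (is(object, "AugmentedADCVolume")) "a.u." else "1e-3 mm^2/s"
  cat(sprintf("%s map, direction '%s': %dx%dx%d, range [%.3g, %.3g] %s\n",
              kind, object@direction, d[1], d[2], d[3],
              min(object@values), max(object@values), unit))
})

setMethod("show", "LesionAnnotation", function(object) {
  areas <- vapply(object@roiBySlice, sum, 0)
  cat(sprintf(
    "LesionAnnotation '%s' (reader %s, %s): %d slice(s), index slice %d (%d px)\n",
    object@lesionId, object@readerId, object@label,
    length(object@roiBySlice), object@indexSlice,
    sum(roiMask(object))))
})

setMethod("show", "VOIMask3D", function(object) {
  cat(sprintf(
    "VOIMask3D direction '%s': %d voxels, threshold %.4g, connectivity %d%s\n",
    object@direction, sum(object@mask), object@threshold,
    object@connectivity, if (object@modeled) "" else " [unmodeled]"))
})

setMethod("show", "SubROIPair", function(object) {
  cat(sprintf("SubROIPair direction '%s': core %d px, peri %d px\n",
              object@direction, sum(object@core), sum(object@peri)))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult (%s): AUC %.3f (empirical %.3f), n+=%d n-=%d\n",
              object@method, object@auc, object@aucEmpirical,
              object@nPos, object@nNeg))
  if (length(object@sensAtSpec))
    cat(sprintf("  sensitivity at specificity %s: %s\n",
                paste(names(object@sensAtSpec), collapse = "/"),
                paste(sprintf("%.3f", object@sensAtSpec), collapse = "/")))
})
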