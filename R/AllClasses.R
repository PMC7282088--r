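#' @include dwicadx-package.R
NULL

DIRECTIONS <- c("r", "p", "s")

## ---------------------------------------------------------------------------
## DWISeries
## ---------------------------------------------------------------------------

#' DWISeries: one b=0 volume plus three directional high-b volumes
#'
#' Container for the raw diffusion-weighted data of a single lesion: the
#' b = 0 s/mm^2 signal volume \code{s0} and one volume per diffusion-encoding
#' gradient direction (\code{r} readout, \code{p} phase, \code{s} slice) at
#' \code{bHigh} s/mm^2, together with the voxel spacing in mm. All four
#' volumes share one grid; slices are indexed along the third axis
#' (1-based).
#'
#' @slot s0 3D numeric array, b=0 signal (arbitrary units, non-negative).
#' @slot sHigh named list of 3D arrays (\code{r}, \code{p}, \code{s}),
#'   high-b signal per direction.
#' @slot bHigh diffusion weighting of the directional volumes, s/mm^2.
#' @slot spacing voxel spacing \code{(dx, dy, dz)} in mm.
#' @slot lesionId lesion identifier.
#'
#' @seealso [readDWISeries()], [computeDirectionalADC()]
#' @export
setClass("DWISeries",
  representation(s0 = "array", sHigh = "list", bHigh = "numeric",
                 spacing = "numeric", lesionId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@s0)) != 3L)
      msg <- c(msg, "s0 must be a 3D array")
    if (!identical(sort(names(object@sHigh)), sort(DIRECTIONS)))
      msg <- c(msg, "sHigh must be a named list with elements r, p, s")
    for (d in names(object@sHigh)) {
      if (!identical(dim(object@sHigh[[d]]), dim(object@s0)))
        msg <- c(msg, sprintf("direction '%s' volume shape differs from s0", d))
    }
    vals <- c(object@s0, unlist(object@sHigh, use.names = FALSE))
    if (!all(is.finite(vals)))
      msg <- c(msg, "all intensities must be finite")
    else if (any(vals < 0))
      msg <- c(msg, "all intensities must be >= 0")
    if (length(object@bHigh) != 1L || object@bHigh <= 0)
      msg <- c(msg, "bHigh must be a single positive value")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' Construct a DWISeries
#'
#' Negative raw intensities (noise floor undershoot) are clamped to zero
#' with a warning reporting the number of affected voxels, since the ADC
#' computation requires non-negative signals.
#'
#' @param s0 3D array, b=0 volume.
#' @param sHigh named list (\code{r}, \code{p}, \code{s}) of 3D arrays.
#' @param bHigh b-value of the directional volumes (s/mm^2), default 800.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param lesionId identifier string.
#' @return A [DWISeries-class] object.
#' @export
DWISeries <- function(s0, sHigh, bHigh = 800, spacing = c(1.25, 1.25, 2.5),
                      lesionId = "lesion") {
  nneg <- sum(s0 < 0) + sum(vapply(sHigh, function(v) sum(v < 0), 0))
  if (nneg > 0) {
    warning(sprintf("clamped %d negative voxel(s) to 0", nneg))
    s0[s0 < 0] <- 0
    sHigh <- lapply(sHigh, function(v) { v[v < 0] <- 0; v })
  }
  new("DWISeries", s0 = s0, sHigh = sHigh[DIRECTIONS], bHigh = bHigh,
      spacing = as.numeric(spacing), lesionId = as.character(lesionId))
}

## ---------------------------------------------------------------------------
## ADC volumes
## ---------------------------------------------------------------------------

#' ADCVolume: a directional apparent-diffusion-coefficient map
#'
#' Voxelwise ADC for one diffusion-encoding direction, stored in units of
#' 1e-3 mm^2/s (the breast-DWI convention under which the cancer-like
#' cutoff reads 1.37). Values are non-negative; voxels with non-positive or
#' inverted signals are zero.
#'
#' @slot values 3D numeric array, ADC in 1e-3 mm^2/s.
#' @slot direction one of \code{"r"}, \code{"p"}, \code{"s"}.
#' @slot spacing voxel spacing in mm.
#' @export
setClass("ADCVolume",
  representation(values = "array", direction = "character",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    else if (any(object@values < 0))
      msg <- c(msg, "values must be >= 0")
    if (!object@direction %in% DIRECTIONS)
      msg <- c(msg, "direction must be one of r, p, s")
    if (length(msg)) msg else TRUE
  })

#' AugmentedADCVolume: S0-weighted directional ADC map
#'
#' Voxelwise product of the b=0 signal and the directional ADC. The
#' augmentation restores the T2-weighted lesion conspicuity of the b=0
#' image while keeping the distortion field of the DWI data, and is the
#' intensity field on which the 3D lesion model is grown.
#'
#' @slot values 3D array, arbitrary units (signal x diffusivity).
#' @export
setClass("AugmentedADCVolume", contains = "ADCVolume")

## ---------------------------------------------------------------------------
## Annotations
## ---------------------------------------------------------------------------

#' LesionAnnotation: a reader's hand-drawn ROIs for one lesion
#'
#' Binary lesion masks drawn on the native DWI grid, one per annotated
#' axial slice, with the index slice (the slice carrying the largest ROI)
#' recorded. Slice indices are 1-based positions along the third array
#' axis; \code{roiBySlice} is keyed by the slice index as a character
#' string.
#'
#' @slot lesionId lesion identifier.
#' @slot readerId reader identifier.
#' @slot label \code{"benign"} or \code{"malignant"}.
#' @slot roiBySlice named list of logical matrices, one per annotated slice.
#' @slot indexSlice the annotated slice with the largest ROI.
#' @export
setClass("LesionAnnotation",
  representation(lesionId = "character", readerId = "character",
                 label = "character", roiBySlice = "list",
                 indexSlice = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@label %in% c("benign", "malignant"))
      msg <- c(msg, "label must be 'benign' or 'malignant'")
    if (length(object@roiBySlice) == 0L)
      msg <- c(msg, "roiBySlice must contain at least one slice")
    if (!as.character(object@indexSlice) %in% names(object@roiBySlice))
      msg <- c(msg, "indexSlice must be an annotated slice")
    areas <- vapply(object@roiBySlice, sum, 0)
    if (any(areas == 0))
      msg <- c(msg, "every per-slice mask must be non-empty")
    idx <- as.character(object@indexSlice)
    if (idx %in% names(areas) && any(areas > areas[[idx]]))
      msg <- c(msg, "indexSlice must carry the largest ROI")
    if (length(msg)) msg else TRUE
  })

#' Construct a LesionAnnotation
#'
#' If \code{indexSlice} is missing it is derived as the annotated slice of
#' largest ROI area (ties broken toward the lowest slice index).
#'
#' @param lesionId,readerId identifiers.
#' @param label \code{"benign"} or \code{"malignant"}.
#' @param roiBySlice named list of logical matrices keyed by slice index.
#' @param indexSlice optional index-slice override.
#' @return A [LesionAnnotation-class] object.
#' @export
LesionAnnotation <- function(lesionId, readerId, label, roiBySlice,
                             indexSlice = NULL) {
  roiBySlice <- lapply(roiBySlice, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  names(roiBySlice) <- as.character(as.integer(names(roiBySlice)))
  if (is.null(indexSlice)) {
    areas <- vapply(roiBySlice, sum, 0)
    ord <- order(as.integer(names(roiBySlice)))
    areas <- areas[ord]
    indexSlice <- as.integer(names(areas)[which.max(areas)])
  }
  new("LesionAnnotation", lesionId = as.character(lesionId),
      readerId = as.character(readerId), label = label,
      roiBySlice = roiBySlice, indexSlice = as.integer(indexSlice))
}

## ---------------------------------------------------------------------------
## Lesion model
## ---------------------------------------------------------------------------

#' VOIMask3D: a grown 3D lesion volume model
#'
#' The connected component, under the stated voxel connectivity, of
#' voxels whose augmented ADC exceeds the selected threshold, grown from a
#' seed voxel inside the hand-drawn ROI. \code{modeled} is FALSE when no
#' candidate threshold achieved a positive Jaccard index against the hand
#' ROI (the lesion could not be modeled; the mask is then empty).
#'
#' @slot mask 3D logical array.
#' @slot direction diffusion-encoding direction the model was grown on.
#' @slot threshold augmented-ADC threshold used (strict: voxels > threshold).
#' @slot seed seed voxel (x, y, z), 1-based.
#' @slot connectivity 6, 18 or 26.
#' @slot modeled logical flag.
#' @export
setClass("VOIMask3D",
  representation(mask = "array", direction = "character",
                 threshold = "numeric", seed = "integer",
                 connectivity = "integer", modeled = "logical"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3D logical array")
    if (!object@connectivity %in% c(6L, 18L, 26L))
      msg <- c(msg, "connectivity must be 6, 18 or 26")
    if (length(object@seed) != 3L)
      msg <- c(msg, "seed must be (x, y, z)")
    if (length(msg)) msg else TRUE
  })

#' SubROIPair: lesion-core and peri-lesion sub-ROIs on the index slice
#'
#' The core is the overlap of the hand-drawn index-slice ROI with the 3D
#' lesion model's cross-section; the periphery is the remainder of the
#' hand-drawn ROI. The two masks partition the hand ROI.
#'
#' @slot core 2D logical matrix.
#' @slot peri 2D logical matrix.
#' @slot direction diffusion-encoding direction.
#' @export
setClass("SubROIPair",
  representation(core = "matrix", peri = "matrix", direction = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@core), dim(object@peri)))
      msg <- c(msg, "core and peri must share a grid")
    if (any(object@core & object@peri))
      msg <- c(msg, "core and peri must be disjoint")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Interpolated-grid annotation
## ---------------------------------------------------------------------------

#' HiResROI: a hand-drawn ROI on an interpolated display grid
#'
#' Readers annotate on interpolated images; the mask must be down-sampled
#' to the native DWI grid before analysis. Carries the annotation-tool
#' recorded area (cm^2) used by the adaptive down-sampling rule, the
#' native grid shape and the native pixel spacing.
#'
#' @slot mask logical matrix on the interpolated grid.
#' @slot nativeShape integer (rows, cols) of the native grid.
#' @slot pixelSpacing native pixel spacing (dx, dy) in mm.
#' @slot recordedAreaCm2 area recorded by the annotation tool (cm^2), or NA.
#' @export
setClass("HiResROI",
  representation(mask = "matrix", nativeShape = "integer",
                 pixelSpacing = "numeric", recordedAreaCm2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (sum(object@mask) == 0)
      msg <- c(msg, "mask must be non-empty")
    if (any(dim(object@mask) < object@nativeShape))
      msg <- c(msg, "interpolated grid must be at least as large as native")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
      msg <- c(msg, "pixelSpacing must be two positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' Construct a HiResROI
#' @param mask logical matrix on the interpolated grid.
#' @param nativeShape native grid shape (rows, cols).
#' @param pixelSpacing native pixel spacing (dx, dy), mm.
#' @param recordedAreaCm2 annotation-tool area in cm^2 (NA if not recorded).
#' @return A [HiResROI-class] object.
#' @export
HiResROI <- function(mask, nativeShape, pixelSpacing = c(1.25, 1.25),
                     recordedAreaCm2 = NA_real_) {
  storage.mode(mask) <- "logical"
  new("HiResROI", mask = mask, nativeShape = as.integer(nativeShape),
      pixelSpacing = as.numeric(pixelSpacing),
      recordedAreaCm2 = as.numeric(recordedAreaCm2))
}

## ---------------------------------------------------------------------------
## ROC
## ---------------------------------------------------------------------------

#' ROCResult: binormal ROC fit for one classifier score
#'
#' Binormal model: scores are Gaussian within each class; with
#' \eqn{a = (\mu_+ - \mu_-)/\sigma_+} and \eqn{b = \sigma_-/\sigma_+} the
#' curve is \eqn{TPF(FPF) = \Phi(a + b\,\Phi^{-1}(FPF))} and
#' \eqn{AUC = \Phi(a/\sqrt{1+b^2})}. When a within-class standard
#' deviation is zero the binormal model is undefined and the object falls
#' back to the empirical ROC (\code{method = "empirical"}, \code{a}/\code{b}
#' are NA).
#'
#' @slot a binormal intercept parameter.
#' @slot b binormal slope parameter (> 0 when binormal).
#' @slot auc area under the fitted curve.
#' @slot aucEmpirical rank-based (Mann-Whitney) empirical AUC.
#' @slot sensAtSpec named numeric, sensitivity at the requested specificities.
#' @slot scores,labels the data the fit used.
#' @slot nPos,nNeg class sizes.
#' @slot method \code{"binormal"} or \code{"empirical"}.
#' @export
setClass("ROCResult",
  representation(a = "numeric", b = "numeric", auc = "numeric",
                 aucEmpirical = "numeric", sensAtSpec = "numeric",
                 scores = "numeric", labels = "character",
                 nPos = "integer", nNeg = "integer", method = "character"),
  validity = function(object) {
    msg <- character()
    if (object@auc < 0 || object@auc > 1)
      msg <- c(msg, "auc must lie in [0, 1]")
    if (object@method == "binormal") {
      if (!is.na(object@b) && object@b <= 0)
        msg <- c(msg, "binormal slope b must be positive")
      if (abs(object@auc - pnorm(object@a / sqrt(1 + object@b^2))) > 1e-8)
        msg <- c(msg, "auc inconsistent with binormal parameters")
    }
    if (length(msg)) msg else TRUE
  })
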