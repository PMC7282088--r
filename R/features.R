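#' @include AllClasses.R
NULL

#' Classify ROI voxels as cancer-like or benign-like
#'
#' Partitions a 2D ROI on one slice of a directional ADC map at the fixed
#' cutoff (default 1.37, in 1e-3 mm^2/s): voxels with ADC strictly below
#' the cutoff are cancer-like, voxels at or above it are benign-like.
#'
#' @param adc an [ADCVolume-class].
#' @param roi logical matrix on the slice grid.
#' @param slice slice index (third axis, 1-based).
#' @param cutoff ADC cutoff in 1e-3 mm^2/s.
#' @return List of logical matrices \code{cancer} and \code{benign}
#'   partitioning \code{roi}.
#' @export
classifyVoxels <- function(adc, roi, slice, cutoff = 1.37) {
  vals <- adc@values[, , as.integer(slice)]
  if (!identical(dim(vals), dim(roi))) stop("ROI grid mismatch")
  list(cancer = roi & vals < cutoff, benign = roi & vals >= cutoff)
}

#' SDAC: directional spread of cancer-like area in the lesion core
#'
#' The sample standard deviation (n-1 denominator) of the cancer-like
#' areas measured in the three directional lesion-core sub-ROIs. Larger
#' values indicate directionally anisotropic restricted diffusion and
#' orient toward malignancy. When the mean cancer-like area is below
#' \code{minMean} (6.67 mm^2, i.e. a three-direction total below 20 mm^2)
#' the cancer-like voxels are considered spurious and SDAC is forced to
#' exactly 0.
#'
#' @param coreAreas numeric vector of three per-direction cancer-like
#'   areas, mm^2.
#' @param minMean forced-zero threshold on the mean area, mm^2.
#' @return SDAC in mm^2 (>= 0).
#' @examples
#' computeSDAC(c(5, 6, 4))   # mean 5 < 6.67 -> 0
#' computeSDAC(c(4, 8, 12))  # 4
#' @export
computeSDAC <- function(coreAreas, minMean = 6.67) {
  if (length(coreAreas) != 3L) stop("expected three directional areas")
  if (mean(coreAreas) < minMean) return(0)
  sd(coreAreas)
}

#' ACMB: cancer-minus-benign area in the lesion periphery
#'
#' Sum over the three directions of (cancer-like area - benign-like area)
#' in the peri-lesion sub-ROIs; negative values are permitted and orient
#' toward benignity.
#'
#' @param periCancer,periBenign numeric vectors of three per-direction
#'   areas, mm^2.
#' @return ACMB in mm^2.
#' @export
computeACMB <- function(periCancer, periBenign) {
  if (length(periCancer) != 3L || length(periBenign) != 3L)
    stop("expected three directional areas")
  sum(periCancer - periBenign)
}

#' Baseline classifier: mean ADC over the hand-drawn ROIs
#'
#' The reference discriminator is the mean ADC over a reader's hand-drawn
#' ROI voxels. The three directional ADC maps are averaged voxelwise (the
#' standard trace-ADC surrogate) and the mean is taken over every
#' annotated slice's ROI (a reader who annotated only the index slice
#' contributes that slice alone).
#'
#' @param adcByDirection named list (\code{r}, \code{p}, \code{s}) of
#'   [ADCVolume-class] objects.
#' @param ann a [LesionAnnotation-class].
#' @return Mean ADC in 1e-3 mm^2/s.
#' @export
meanADCBaseline <- function(adcByDirection, ann) {
  avg <- (adcByDirection$r@values + adcByDirection$p@values +
          adcByDirection$s@values) / 3
  vals <- unlist(lapply(names(ann@roiBySlice), function(k) {
    avg[, , as.integer(k)][ann@roiBySlice[[k]]]
  }), use.names = FALSE)
  mean(vals)
}

#' Full per-lesion feature extraction for one reader
#'
#' Runs the model-based analysis for every diffusion-encoding direction:
#' computes the directional and augmented ADC maps, grows the
#' Jaccard-maximized 3D lesion model, splits the hand ROI into core and
#' periphery, classifies the sub-ROI voxels at the ADC cutoff, and
#' derives SDAC, ACMB and the baseline mean ADC.
#'
#' @param series a [DWISeries-class].
#' @param ann the reader's [LesionAnnotation-class].
#' @param cutoff cancer-like ADC cutoff, 1e-3 mm^2/s.
#' @param minMeanCoreArea SDAC forced-zero threshold, mm^2.
#' @param connectivity region-growing connectivity.
#' @param adcByDirection,auByDirection optional precomputed maps (shared
#'   across readers of one lesion).
#' @param ... passed to [selectThreshold()].
#' @return A list: \code{features} (one-row data frame with lesion id,
#'   reader id, label, sdac, acmb, mean_adc, per-direction areas, mean
#'   model Jaccard and the index-slice ROI area in cm^2) and
#'   \code{subROIs} (named list of [SubROIPair-class] per direction).
#' @export
lesionFeatures <- function(series, ann, cutoff = 1.37, minMeanCoreArea = 6.67,
                           connectivity = 26, adcByDirection = NULL,
                           auByDirection = NULL, ...) {
  if (is.null(adcByDirection))
    adcByDirection <- sapply(DIRECTIONS, function(d)
      computeDirectionalADC(series, d), simplify = FALSE)
  if (is.null(auByDirection))
    auByDirection <- sapply(DIRECTIONS, function(d)
      computeAugmentedADC(series, adcByDirection[[d]]), simplify = FALSE)

  idx <- ann@indexSlice
  hand <- roiMask(ann, idx)
  sp <- series@spacing[1:2]

  coreCancer <- periCancer <- periBenign <- jac <-
    structure(numeric(3), names = DIRECTIONS)
  subROIs <- list()
  for (d in DIRECTIONS) {
    sel <- selectThreshold(auByDirection[[d]], hand, idx,
                           connectivity = connectivity, ...)
    pair <- splitCorePeri(sel$voi, hand, idx)
    subROIs[[d]] <- pair
    jac[d] <- sel$jaccard
    cc <- classifyVoxels(adcByDirection[[d]], pair@core, idx, cutoff)
    pc <- classifyVoxels(adcByDirection[[d]], pair@peri, idx, cutoff)
    coreCancer[d] <- maskArea(cc$cancer, sp)
    periCancer[d] <- maskArea(pc$cancer, sp)
    periBenign[d] <- maskArea(pc$benign, sp)
  }

  feats <- data.frame(
    lesion_id = ann@lesionId, reader_id = ann@readerId, label = ann@label,
    sdac = computeSDAC(coreCancer, minMeanCoreArea),
    acmb = computeACMB(periCancer, periBenign),
    mean_adc = meanADCBaseline(adcByDirection, ann),
    core_cancer_r = coreCancer["r"], core_cancer_p = coreCancer["p"],
    core_cancer_s = coreCancer["s"],
    peri_cancer_r = periCancer["r"], peri_cancer_p = periCancer["p"],
    peri_cancer_s = periCancer["s"],
    peri_benign_r = periBenign["r"], peri_benign_p = periBenign["p"],
    peri_benign_s = periBenign["s"],
    mean_jaccard = mean(jac),
    roi_area_cm2 = maskArea(hand, sp, "cm2"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(features = feats, subROIs = subROIs)
}
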