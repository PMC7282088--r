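#' @include AllClasses.R
NULL

#' Pipeline run configuration
#'
#' Collects the tunable constants of the end-to-end analysis: the
#' cancer-like ADC cutoff (1.37, 1e-3 mm^2/s), the SDAC forced-zero
#' minimum mean core area (6.67 mm^2), the cohort ROI-size exclusion
#' limit (7.50 cm^2), the region-growing connectivity, the
#' cross-validation settings and the master seed.
#'
#' @param cutoffADC cancer-like ADC cutoff, 1e-3 mm^2/s.
#' @param minMeanCoreArea SDAC forced-zero threshold, mm^2.
#' @param maxRoiAreaCm2 cohort exclusion limit, cm^2.
#' @param connectivity 6, 18 or 26.
#' @param nFolds,nRepeats cross-validation settings.
#' @param seed master seed.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(cutoffADC = 1.37, minMeanCoreArea = 6.67,
                      maxRoiAreaCm2 = 7.50, connectivity = 26,
                      nFolds = 5, nRepeats = 20, seed = 1) {
  stopifnot(cutoffADC > 0, minMeanCoreArea > 0, maxRoiAreaCm2 > 0)
  structure(list(cutoffADC = cutoffADC, minMeanCoreArea = minMeanCoreArea,
                 maxRoiAreaCm2 = maxRoiAreaCm2,
                 connectivity = as.integer(connectivity),
                 nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Extract features and sub-ROIs for every lesion and reader of a cohort
#'
#' Shares the directional ADC and augmented ADC maps across a lesion's
#' readers and runs [lesionFeatures()] per reader.
#'
#' @param cohortData a cohort as produced by [generateCohort()].
#' @param config a [runConfig()].
#' @return A list: \code{features} (data frame, one row per lesion x
#'   reader) and \code{subROIs} (nested list lesion -> reader ->
#'   direction of [SubROIPair-class]).
#' @export
cohortFeatures <- function(cohortData, config = runConfig()) {
  featRows <- list(); subROIs <- list()
  for (les in cohortData$lesions) {
    adc <- sapply(DIRECTIONS, function(d)
      computeDirectionalADC(les$series, d), simplify = FALSE)
    au <- sapply(DIRECTIONS, function(d)
      computeAugmentedADC(les$series, adc[[d]]), simplify = FALSE)
    lid <- les$series@lesionId
    subROIs[[lid]] <- list()
    for (ann in les$annotations) {
      lf <- lesionFeatures(les$series, ann, cutoff = config$cutoffADC,
                           minMeanCoreArea = config$minMeanCoreArea,
                           connectivity = config$connectivity,
                           adcByDirection = adc, auByDirection = au)
      featRows[[length(featRows) + 1L]] <- lf$features
      subROIs[[lid]][[ann@readerId]] <- lf$subROIs
    }
  }
  list(features = do.call(rbind, c(featRows, list(make.row.names = FALSE))),
       subROIs = subROIs)
}

## assemble the per-lesion mask pairs the agreement analysis needs
.agreementInput <- function(cohortData, subROIs) {
  lapply(cohortData$lesions, function(les) {
    lid <- les$series@lesionId
    readers <- names(les$annotations)
    a1 <- les$annotations[[readers[1]]]
    a2 <- les$annotations[[readers[2]]]
    s1 <- subROIs[[lid]][[readers[1]]]
    s2 <- subROIs[[lid]][[readers[2]]]
    # hand-ROI comparison on Reader 1's index slice; Reader 2's mask is
    # overlaid in-plane (their own index slice if it differs)
    h2 <- tryCatch(roiMask(a2, indexSlice(a1)),
                   error = function(e) roiMask(a2))
    list(lesion_id = lid, label = les$label,
         hand1 = roiMask(a1), hand2 = h2,
         core1 = lapply(s1, coreMask), core2 = lapply(s2, coreMask),
         area_mm2 = maskArea(roiMask(a1), les$series@spacing[1:2]))
  })
}

#' Run the complete analysis pipeline on a synthetic cohort
#'
#' Simulation, ADC mapping, lesion modeling, feature extraction, cohort
#' size filtering, ROC evaluation and inter-observer agreement in one
#' call. Fully deterministic under the configuration seed.
#'
#' @param config a [runConfig()].
#' @param nBenign,nMalignant cohort class sizes.
#' @param null generate the matched null cohort (identical class
#'   parameters) instead of the anisotropic-malignant one.
#' @param cohortData optional pre-generated cohort (skips simulation).
#' @param ... passed to [generateCohort()].
#' @return A list: \code{features}, \code{evaluation} (from
#'   [evaluatePipeline()]), \code{agreement} (from
#'   [agreementAnalysis()]), \code{cohort}, \code{config}.
#' @export
runPipeline <- function(config = runConfig(), nBenign = 29, nMalignant = 34,
                        null = FALSE, cohortData = NULL, ...) {
  if (is.null(cohortData))
    cohortData <- generateCohort(nBenign, nMalignant, seed = config$seed,
                                 null = null, ...)
  cf <- cohortFeatures(cohortData, config)
  feats <- cf$features

  kept <- filterCohort(
    data.frame(lesion_id = feats$lesion_id, reader_id = feats$reader_id,
               label = feats$label, roi_area_cm2 = feats$roi_area_cm2,
               stringsAsFactors = FALSE),
    maxAreaCm2 = config$maxRoiAreaCm2)
  if (!nrow(kept)) stop("empty cohort after ROI-size filtering")
  feats <- feats[feats$lesion_id %in% kept$lesion_id, , drop = FALSE]

  evaluation <- evaluatePipeline(
    feats, cv = cvConfig(nFolds = config$nFolds, nRepeats = config$nRepeats,
                         seed = config$seed))

  keepLes <- vapply(cohortData$lesions, function(l)
    l$series@lesionId %in% kept$lesion_id, TRUE)
  agreement <- agreementAnalysis(
    .agreementInput(list(lesions = cohortData$lesions[keepLes]), cf$subROIs))

  list(features = feats, evaluation = evaluation, agreement = agreement,
       cohort = cohortData$cohort, config = config)
}
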