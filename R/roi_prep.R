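#' @include AllClasses.R
NULL

## overlap matrix between native and interpolated pixel intervals along one
## axis: M[i, j] = share of native cell i's footprint covered by hi cell j
## (rows sum to 1) under uniform rescaling of both grids to one extent.
.overlapMatrix <- function(nNative, nHi) {
  scale <- nHi / nNative
  lo <- (seq_len(nNative) - 1) * scale
  hi <- seq_len(nNative) * scale
  jlo <- seq_len(nHi) - 1
  jhi <- seq_len(nHi)
  ov <- pmin(outer(hi, jhi, function(a, b) a),
             outer(rep(1, nNative), jhi)) -
        pmax(outer(lo, jlo, function(a, b) a),
             outer(rep(1, nNative), jlo))
  ov[ov < 0] <- 0
  ov / scale
}

#' Contribution fractions of an interpolated ROI on the native grid
#'
#' Readers draw ROIs on interpolated display images; each native DWI pixel
#' receives signal contributions from several interpolated pixels. This
#' computes, for every native pixel, the fraction of its geometric
#' footprint (after uniformly rescaling the two rectangular grids onto the
#' same physical extent) covered by in-ROI interpolated pixels. Fractions
#' lie in [0, 1]; their sum times the native pixel area equals the hi-res
#' ROI's physical area (area conservation). When the interpolated shape is
#' an integer multiple of the native shape this reduces to block
#' averaging.
#'
#' @param hi a [HiResROI-class].
#' @return Numeric matrix of fractions with the native grid shape.
#' @export
contributionFractions <- function(hi) {
  m <- hi@mask
  ns <- hi@nativeShape
  Mr <- .overlapMatrix(ns[1], nrow(m))
  Mc <- .overlapMatrix(ns[2], ncol(m))
  fr <- Mr %*% (m * 1) %*% t(Mc)
  fr[fr > 1] <- 1
  fr[fr < 0] <- 0
  fr
}

#' Down-sample an interpolated ROI by majority rule
#'
#' A native pixel enters the down-sampled ROI when at least
#' \code{cutoff} (default 50\%) of its contributing interpolated pixels are
#' in the hand-drawn ROI — the rule used for annotations drawn on a
#' fixed-size interpolated template. An annotation whose down-sampling is
#' empty has been lost and raises an error.
#'
#' @param hi a [HiResROI-class].
#' @param cutoff inclusion fraction, default 0.5 (inclusive: a pixel at
#'   exactly the cutoff is included).
#' @return Logical matrix on the native grid.
#' @export
downsampleMajority <- function(hi, cutoff = 0.5) {
  fr <- contributionFractions(hi)
  mask <- fr >= cutoff
  if (!any(mask))
    stop("annotation lost in down-sampling (empty result)")
  mask
}

#' Down-sample an interpolated ROI by the adaptive-percentage rule
#'
#' For annotations whose tool recorded the drawn ROI area in cm^2, the
#' inclusion percentage is chosen per case so that the down-sampled ROI's
#' physical area is closest to the recorded area. All distinct positive
#' contribution fractions are scanned as candidate cutoffs; ties in area
#' error are broken toward the lower cutoff (the larger mask, preserving
#' lesion tissue). If the empty mask beats every candidate (e.g. a
#' recorded area of 0) the annotation is considered lost and an error is
#' raised.
#'
#' @param hi a [HiResROI-class] with \code{recordedAreaCm2} set.
#' @return A list with elements \code{mask} (logical native-grid matrix)
#'   and \code{cutoff} (the selected inclusion fraction).
#' @export
downsampleAdaptive <- function(hi) {
  if (is.na(hi@recordedAreaCm2))
    stop("adaptive down-sampling needs the recorded ROI area (cm^2)")
  fr <- contributionFractions(hi)
  cand <- sort(unique(fr[fr > 0]))
  if (!length(cand))
    stop("annotation lost in down-sampling (empty result)")
  pxArea <- hi@pixelSpacing[1] * hi@pixelSpacing[2] / 100  # cm^2
  areas <- vapply(cand, function(co) sum(fr >= co) * pxArea, 0)
  err <- abs(areas - hi@recordedAreaCm2)
  # the empty mask (area 0) is an implicit candidate; if it strictly beats
  # every non-empty cutoff the annotation has been lost
  if (abs(0 - hi@recordedAreaCm2) < min(err))
    stop("annotation lost in down-sampling (empty result)")
  best <- which(err == min(err))[1]  # cand is ascending: first = lower cutoff
  list(mask = fr >= cand[best], cutoff = cand[best])
}

#' Select the index slice of an annotation
#'
#' The index slice is the annotated axial slice carrying the largest
#' hand-drawn ROI; ties are broken toward the lowest slice index.
#'
#' @param ann a [LesionAnnotation-class].
#' @return Integer slice index.
#' @export
selectIndexSlice <- function(ann) {
  slices <- as.integer(names(ann@roiBySlice))
  ord <- order(slices)
  areas <- vapply(ann@roiBySlice, sum, 0)[ord]
  slices[ord][which.max(areas)]
}

#' Filter a cohort by index-slice ROI size
#'
#' Lesions whose index-slice hand-drawn ROI exceeds \code{maxAreaCm2}
#' (default 7.50 cm^2) are removed from the cohort; the reference area per
#' lesion is the one recorded for the lowest reader id (the fully informed
#' reader), falling back to the row's own area. Exclusions are reported
#' with a message.
#'
#' @param cohort cohort data frame with columns \code{lesion_id},
#'   \code{reader_id}, \code{label} and \code{roi_area_cm2}.
#' @param maxAreaCm2 exclusion threshold in cm^2.
#' @return The filtered cohort data frame.
#' @export
filterCohort <- function(cohort, maxAreaCm2 = 7.50) {
  validateCohort(cohort)
  if (!nrow(cohort)) return(cohort)
  if (!"roi_area_cm2" %in% names(cohort))
    stop("cohort must carry roi_area_cm2 for size filtering")
  ref <- vapply(split(cohort, cohort$lesion_id), function(g) {
    g$roi_area_cm2[order(g$reader_id)][1]
  }, 0)
  drop <- names(ref)[ref > maxAreaCm2]
  if (length(drop))
    message(sprintf("excluding %d lesion(s) with ROI > %.2f cm^2: %s",
                    length(drop), maxAreaCm2, paste(drop, collapse = ", ")))
  cohort[!cohort$lesion_id %in% drop, , drop = FALSE]
}
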