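#' @include AllClasses.R
NULL

#' Jaccard similarity index of two binary masks
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}; defined as 0 when both masks
#' are empty. Used to score a lesion model's index-slice cross-section
#' against the hand-drawn ROI.
#'
#' @param a,b logical masks of identical shape.
#' @return Fraction in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Grow a 3D lesion volume model by threshold region growing
#'
#' Returns the connected component, under the requested voxel
#' connectivity, of \{voxels with augmented ADC strictly greater than
#' \code{threshold}\} that contains the seed; the mask is empty when the
#' seed itself fails the threshold. The grown model is topologically
#' connected in 3D but its 2D cross-sections need not be connected.
#'
#' @param au an [AugmentedADCVolume-class].
#' @param seed seed voxel \code{(x, y, z)}, 1-based.
#' @param threshold strict lower intensity bound.
#' @param connectivity 6, 18 or 26 (default) neighborhood.
#' @return A [VOIMask3D-class].
#' @export
growVOI <- function(au, seed, threshold, connectivity = 26) {
  d <- dim(au@values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed out of bounds")
  lin <- seed[1] + d[1] * ((seed[2] - 1) + d[2] * (seed[3] - 1))
  comp <- .cc_from_seed(as.numeric(au@values), d, lin, threshold,
                        as.integer(connectivity))
  new("VOIMask3D", mask = array(comp, dim = d), direction = au@direction,
      threshold = as.numeric(threshold), seed = seed,
      connectivity = as.integer(connectivity), modeled = any(comp))
}

## dilate the hand-ROI bounding box by `pad` pixels in-plane (all slices)
.paddedBox <- function(mask, pad, dims) {
  ij <- which(mask, arr.ind = TRUE)
  rx <- c(max(1L, min(ij[, 1]) - pad), min(dims[1], max(ij[, 1]) + pad))
  ry <- c(max(1L, min(ij[, 2]) - pad), min(dims[2], max(ij[, 2]) + pad))
  list(x = rx[1]:rx[2], y = ry[1]:ry[2])
}

#' Select the region-growing threshold by Jaccard maximization
#'
#' Grows the 3D lesion model at every candidate threshold and keeps the
#' threshold whose model cross-section in the index slice best matches the
#' hand-drawn ROI by Jaccard index; ties are broken toward the lowest
#' threshold (the largest model). The seed is the voxel of maximum
#' augmented ADC within the hand ROI on the index slice (ties:
#' lexicographically smallest index). Candidate thresholds are the
#' distinct augmented-ADC values inside the hand ROI's bounding box
#' dilated by \code{dilatePx} pixels in-plane across all slices (plus one
#' threshold below their minimum so the all-inclusive model is reachable),
#' capped at \code{maxCandidates} evenly spaced quantiles; the model is
#' grown within that padded box. If no candidate achieves a positive
#' Jaccard the lesion is flagged unmodeled and an empty model is returned.
#'
#' @param au an [AugmentedADCVolume-class].
#' @param handROI logical matrix, hand-drawn ROI on the index slice.
#' @param indexSlice slice index (1-based, third axis).
#' @param connectivity 6, 18 or 26.
#' @param dilatePx in-plane bounding-box dilation, default 5.
#' @param maxCandidates cap on the candidate-threshold count, default 512.
#' @return A list: \code{threshold}, \code{jaccard}, \code{voi}
#'   ([VOIMask3D-class]), \code{seed}.
#' @export
selectThreshold <- function(au, handROI, indexSlice, connectivity = 26,
                            dilatePx = 5, maxCandidates = 512) {
  d <- dim(au@values)
  if (!identical(dim(handROI), d[1:2])) stop("hand ROI grid mismatch")
  if (!any(handROI)) stop("hand ROI is empty")
  indexSlice <- as.integer(indexSlice)

  sliceVals <- au@values[, , indexSlice]
  inROI <- which(handROI)
  seedLin2 <- inROI[which.max(sliceVals[inROI])]  # which.max: first = smallest index
  seed <- c(arrayInd(seedLin2, d[1:2]), indexSlice)

  box <- .paddedBox(handROI, as.integer(dilatePx), d)
  sub <- au@values[box$x, box$y, , drop = FALSE]
  subROI <- handROI[box$x, box$y]
  sd_ <- dim(sub)
  seedSub <- c(match(seed[1], box$x), match(seed[2], box$y), indexSlice)
  seedLin <- seedSub[1] + sd_[1] * ((seedSub[2] - 1) + sd_[2] * (seedSub[3] - 1))

  uv <- sort(unique(as.numeric(sub)))
  if (length(uv) > maxCandidates)
    uv <- sort(unique(quantile(as.numeric(sub),
                               probs = seq(0, 1, length.out = maxCandidates),
                               names = FALSE, type = 1)))
  eps <- if (length(uv) > 1) min(diff(uv)) / 2 else max(abs(uv[1]), 1) * 1e-9
  cand <- c(uv[1] - eps, uv)

  subVec <- as.numeric(sub)
  candDesc <- rev(cand)  # one union-find sweep over descending thresholds
  jacs <- .jaccard_scan(subVec, sd_, seedLin, candDesc,
                        as.logical(subROI), indexSlice,
                        as.integer(connectivity))
  jBest <- max(jacs)
  tBest <- min(candDesc[jacs == jBest])  # tie: lowest threshold, largest VOI
  best <- list(j = jBest, t = tBest,
               comp = .cc_from_seed(subVec, sd_, seedLin, tBest,
                                    as.integer(connectivity)))

  modeled <- best$j > 0
  mask <- array(FALSE, dim = d)
  if (modeled)
    mask[box$x, box$y, ] <- array(best$comp, dim = sd_)
  thr <- if (modeled) best$t else uv[length(uv)]
  voi <- new("VOIMask3D", mask = mask, direction = au@direction,
             threshold = thr, seed = as.integer(seed),
             connectivity = as.integer(connectivity), modeled = modeled)
  list(threshold = thr, jaccard = max(best$j, 0), voi = voi,
       seed = as.integer(seed))
}

#' Split a hand-drawn ROI into lesion-core and peri-lesion sub-ROIs
#'
#' The lesion core is the overlap of the hand-drawn index-slice ROI with
#' the 3D lesion model's cross-section in that slice; the peri-lesion
#' sub-ROI is the remainder of the hand-drawn ROI. Together they
#' partition the hand ROI.
#'
#' @param voi a [VOIMask3D-class].
#' @param handROI logical matrix on the index slice.
#' @param indexSlice slice index.
#' @return A [SubROIPair-class].
#' @export
splitCorePeri <- function(voi, handROI, indexSlice) {
  cross <- voi@mask[, , as.integer(indexSlice)]
  if (!identical(dim(cross), dim(handROI))) stop("grid mismatch")
  core <- handROI & cross
  peri <- handROI & !core
  new("SubROIPair", core = core, peri = peri, direction = voi@direction)
}
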