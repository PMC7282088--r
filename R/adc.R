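#' @include AllClasses.R
NULL

#' Compute a directional ADC map
#'
#' Voxelwise apparent diffusion coefficient for one diffusion-encoding
#' direction, \eqn{ADC_d = (1/b) \ln(S_0 / S_{d,b})}, converted to the
#' breast-DWI storage unit 1e-3 mm^2/s (so typical tissue values read
#' 0.5--3 and the cancer-like cutoff reads 1.37). Voxels where either
#' signal is non-positive, or where \eqn{S_{d,b} > S_0} (a negative ADC,
#' i.e. noise), are set to 0; the number of such clamped-negative voxels is
#' recorded in the \code{"nClampedNegative"} attribute for QC.
#'
#' @param series a [DWISeries-class].
#' @param direction one of \code{"r"}, \code{"p"}, \code{"s"}.
#' @return An [ADCVolume-class] in 1e-3 mm^2/s.
#' @examples
#' s0 <- array(1000, c(4, 4, 2))
#' sh <- list(r = array(900, c(4, 4, 2)), p = array(1000, c(4, 4, 2)),
#'            s = array(exp(-1) * 1000, c(4, 4, 2)))
#' ser <- DWISeries(s0, sh, bHigh = 800)
#' adcValues(computeDirectionalADC(ser, "s"))[1, 1, 1]  # 1/800 mm^2/s = 1.25
#' @export
computeDirectionalADC <- function(series, direction = c("r", "p", "s")) {
  direction <- match.arg(direction)
  s0 <- series@s0
  sd_ <- series@sHigh[[direction]]
  adc <- array(0, dim = dim(s0))
  ok <- s0 > 0 & sd_ > 0
  adc[ok] <- (1 / series@bHigh) * log(s0[ok] / sd_[ok]) * 1e3
  neg <- adc < 0
  adc[neg] <- 0
  out <- new("ADCVolume", values = adc, direction = direction,
             spacing = series@spacing)
  attr(out@values, "nClampedNegative") <- sum(neg)
  out
}

#' Compute an augmented directional ADC map
#'
#' Voxelwise product of the b=0 signal and the directional ADC,
#' \eqn{auADC_d = S_0 \cdot ADC_d}. The result inherits the T2-weighted
#' lesion conspicuity of the b=0 image and is the intensity field used for
#' 3D lesion-model region growing.
#'
#' @param series the [DWISeries-class] providing \eqn{S_0}.
#' @param adc the matching [ADCVolume-class].
#' @return An [AugmentedADCVolume-class] (arbitrary units).
#' @export
computeAugmentedADC <- function(series, adc) {
  if (!identical(dim(series@s0), dim(adc@values)))
    stop("S0 and ADC grids differ")
  vals <- series@s0 * adc@values
  attr(vals, "nClampedNegative") <- NULL
  new("AugmentedADCVolume", values = vals, direction = adc@direction,
      spacing = adc@spacing)
}
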