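#' @include AllClasses.R
NULL

#' Phantom specification for one synthetic lesion
#'
#' Parameters of the dense-breast DWI phantom. The defaults emulate the
#' acquisition this pipeline targets: a 96x96x20 grid at 1.25 x 1.25 x
#' 2.5 mm, fibroglandular background ADC 1.9 +/- 0.2 (1e-3 mm^2/s), an
#' ellipsoidal lesion whose core ADC is directionally anisotropic for
#' malignant lesions (base 0.9 with per-direction multipliers 1.0 / 1.35
#' / 0.75 for r / p / s) and isotropic (1.6) for benign ones, an
#' infiltrative rim of intermediate signal, an optional high-ADC
#' necrotic/cystic focus inside malignant cores (which degrades the mean
#' ADC baseline, as necrosis does in patients), and Rician magnitude
#' noise.
#'
#' @param dim grid shape (nx, ny, nz).
#' @param spacing voxel spacing, mm.
#' @param label \code{"benign"} or \code{"malignant"} (sets ADC defaults).
#' @param bgADC background ADC mean and SD, 1e-3 mm^2/s.
#' @param center lesion center in mm; default grid center.
#' @param semiAxes ellipsoid semi-axes (mm); \code{NULL} for a
#'   background-only phantom.
#' @param coreADCBase lesion core ADC base value, 1e-3 mm^2/s.
#' @param dirMultipliers per-direction multipliers (r, p, s) applied to
#'   \code{coreADCBase}; the anisotropy dial.
#' @param intraLesionSD voxelwise ADC texture SD inside lesion/rim.
#' @param rimWidth rim thickness, mm.
#' @param rimADC rim ADC, 1e-3 mm^2/s.
#' @param necroticFraction volume fraction of a high-ADC focus in the
#'   core (0 = none).
#' @param necroticADC ADC of the focus, 1e-3 mm^2/s.
#' @param s0Background,s0Rim,s0Lesion b=0 signal levels (a.u.).
#' @param noiseSigma Rician noise sigma (a.u.).
#' @param bHigh high b-value, s/mm^2.
#' @param seed RNG seed.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(dim = c(96, 96, 20), spacing = c(1.25, 1.25, 2.5),
                        label = c("malignant", "benign"),
                        bgADC = c(mean = 1.9, sd = 0.2),
                        center = NULL,
                        semiAxes = c(7, 7, 5),
                        coreADCBase = NULL,
                        dirMultipliers = NULL,
                        intraLesionSD = 0.05,
                        rimWidth = 2,
                        rimADC = NULL,
                        necroticFraction = 0,
                        necroticADC = 2.3,
                        s0Background = 300, s0Rim = 700, s0Lesion = 1200,
                        noiseSigma = 15, bHigh = 800, seed = 1) {
  label <- match.arg(label)
  if (is.null(coreADCBase)) coreADCBase <- if (label == "malignant") 0.9 else 1.6
  if (is.null(dirMultipliers))
    dirMultipliers <- if (label == "malignant")
      c(r = 1.0, p = 1.35, s = 0.75) else c(r = 1, p = 1, s = 1)
  if (is.null(rimADC)) rimADC <- if (label == "malignant") 1.25 else 1.7
  if (is.null(center)) center <- dim * spacing / 2
  if (!is.null(semiAxes)) {
    if (any(semiAxes <= 0)) stop("semi-axes must be positive")
    if (any(center - semiAxes - rimWidth < 0) ||
        any(center + semiAxes + rimWidth > dim * spacing))
      stop("lesion (incl. rim) does not fit inside the grid")
  }
  if (any(c(bgADC, coreADCBase, rimADC, necroticADC) <= 0))
    stop("ADC parameters must be positive")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 label = label, bgADC = bgADC, center = as.numeric(center),
                 semiAxes = if (is.null(semiAxes)) NULL else as.numeric(semiAxes),
                 coreADCBase = coreADCBase,
                 dirMultipliers = structure(as.numeric(dirMultipliers),
                                            names = DIRECTIONS),
                 intraLesionSD = intraLesionSD, rimWidth = rimWidth,
                 rimADC = rimADC, necroticFraction = necroticFraction,
                 necroticADC = necroticADC, s0Background = s0Background,
                 s0Rim = s0Rim, s0Lesion = s0Lesion,
                 noiseSigma = noiseSigma, bHigh = bHigh,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

## squared normalized ellipsoid coordinate field
.ellipsoidU <- function(dims, spacing, center, axes) {
  x <- ((seq_len(dims[1]) - 0.5) * spacing[1] - center[1]) / axes[1]
  y <- ((seq_len(dims[2]) - 0.5) * spacing[2] - center[2]) / axes[2]
  z <- ((seq_len(dims[3]) - 0.5) * spacing[3] - center[3]) / axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

.rician <- function(vol, sigma) {
  if (sigma == 0) return(vol)
  n <- length(vol)
  sqrt((vol + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Generate a synthetic DWI phantom
#'
#' Builds the piecewise directional ADC field (background, rim, core,
#' optional necrotic focus), the b=0 signal volume, and the noiseless
#' directional signals \eqn{S_d = S_0 \exp(-b \cdot ADC_d)}; Rician noise
#' is then applied to all four magnitude volumes. At \code{noiseSigma =
#' 0} the pipeline's ADC maps invert the forward model exactly.
#'
#' @param spec a [phantomSpec()].
#' @return A list: \code{series} ([DWISeries-class]), \code{truth} (3D
#'   logical lesion-core mask), \code{label}, and \code{adcField} (named
#'   list of the generative per-direction ADC arrays, 1e-3 mm^2/s).
#' @export
generatePhantom <- function(spec) {
  set.seed(spec$seed)
  d <- spec$dim
  n <- prod(d)

  bg <- array(pmax(rnorm(n, spec$bgADC[["mean"]], spec$bgADC[["sd"]]), 0.2), d)
  texture <- array(rnorm(n, 0, spec$intraLesionSD), d)

  if (!is.null(spec$semiAxes)) {
    uCore <- .ellipsoidU(d, spec$spacing, spec$center, spec$semiAxes)
    uRim <- .ellipsoidU(d, spec$spacing, spec$center,
                        spec$semiAxes + spec$rimWidth)
    core <- uCore <= 1
    rim <- uRim <= 1 & !core
    necro <- array(FALSE, d)
    if (spec$necroticFraction > 0) {
      fAx <- spec$necroticFraction^(1 / 3)
      off <- runif(3, -0.25, 0.25) * spec$semiAxes
      uN <- .ellipsoidU(d, spec$spacing, spec$center + off,
                        fAx * spec$semiAxes)
      necro <- uN <= 1 & core
    }
  } else {
    core <- rim <- necro <- array(FALSE, d)
  }

  adcField <- list()
  for (dname in DIRECTIONS) {
    f <- bg
    f[rim] <- pmax(spec$rimADC + texture[rim], 0.1)
    f[core] <- pmax(spec$coreADCBase * spec$dirMultipliers[[dname]] +
                      texture[core], 0.1)
    f[necro] <- pmax(spec$necroticADC + texture[necro], 0.1)
    adcField[[dname]] <- f
  }

  s0 <- array(spec$s0Background, d)
  s0[rim] <- spec$s0Rim
  s0[core] <- spec$s0Lesion
  sHigh <- lapply(adcField, function(f) s0 * exp(-spec$bHigh * f * 1e-3))

  s0n <- .rician(s0, spec$noiseSigma)
  sHighN <- lapply(sHigh, .rician, sigma = spec$noiseSigma)

  series <- DWISeries(array(s0n, d),
                      lapply(sHighN, array, dim = d),
                      bHigh = spec$bHigh, spacing = spec$spacing,
                      lesionId = sprintf("phantom-%d", spec$seed))
  list(series = series, truth = core, label = spec$label,
       adcField = adcField)
}

## smooth periodic boundary-jitter profile, normalized to max |g| = 1
.jitterProfile <- function(nHarmonics = 3) {
  a <- rnorm(nHarmonics)
  phi <- runif(nHarmonics, 0, 2 * pi)
  function(theta) {
    g <- Reduce(`+`, lapply(seq_len(nHarmonics), function(k)
      a[k] * cos(k * theta + phi[k])))
    m <- max(abs(g))
    if (m == 0) g else g / m
  }
}

#' Simulate a reader's hand-drawn annotation
#'
#' Perturbs the true lesion cross-sections by smooth radial noise: the
#' signed distance to the lesion boundary (via distance transform) is
#' compared against \code{jitterPx} times a smooth periodic angular
#' profile, displacing the drawn contour inward/outward by up to
#' \code{jitterPx} pixels. Slices whose perturbed mask comes out empty
#' are dropped (a reader would not annotate them); a jitter amplitude at
#' or above the lesion's index-slice inradius is rejected. With
#' \code{jitterPx = 0} the annotation equals the true cross-sections.
#'
#' @param truth 3D logical lesion mask.
#' @param slices slice indices the reader annotates; default all
#'   non-empty slices.
#' @param jitterPx boundary perturbation amplitude in pixels.
#' @param seed RNG seed.
#' @param lesionId,readerId,label annotation metadata.
#' @return A [LesionAnnotation-class]; the index slice is the annotated
#'   slice of largest perturbed ROI.
#' @export
simulateReaderROI <- function(truth, slices = NULL, jitterPx = 1, seed = 1,
                              lesionId = "lesion", readerId = "reader",
                              label = "benign") {
  perSlice <- apply(truth, 3, sum)
  if (all(perSlice == 0)) stop("truth mask is empty")
  if (is.null(slices)) slices <- which(perSlice > 0)
  slices <- slices[perSlice[slices] > 0]
  trueIdx <- which.max(perSlice)

  set.seed(seed)
  if (jitterPx > 0) {
    inradius <- max(EBImage::distmap(truth[, , trueIdx] * 1))
    if (jitterPx >= inradius)
      stop("jitter amplitude exceeds the lesion radius")
  }
  g <- .jitterProfile()

  rois <- list()
  for (k in slices) {
    m <- truth[, , k]
    if (jitterPx == 0) {
      rois[[as.character(k)]] <- m
      next
    }
    din <- EBImage::distmap(m * 1)          # distance to background, inside
    dout <- EBImage::distmap((!m) * 1)      # distance to lesion, outside
    sdist <- as.matrix(dout) - as.matrix(din)
    ij <- which(m, arr.ind = TRUE)
    cen <- colMeans(ij)
    theta <- atan2(col(m) - cen[2], row(m) - cen[1])
    pm <- sdist <= jitterPx * g(theta)
    if (any(pm)) rois[[as.character(k)]] <- pm
  }
  if (!length(rois)) stop("annotation empty after perturbation")
  LesionAnnotation(lesionId, readerId, label, rois)
}

#' Generate a synthetic two-reader cohort
#'
#' Draws per-lesion phantom specifications, generates the DWI series and
#' two simulated readers' annotations (Reader 1 annotates every slice
#' containing lesion with small boundary jitter; Reader 2 annotates only
#' the index slice with larger jitter, mimicking a blinded reader), and
#' assembles the cohort table. The default class balance matches the
#' study design this pipeline is built for: 29 benign and 34 malignant
#' lesions. Malignant lesions are directionally anisotropic and carry a
#' random necrotic/cystic high-ADC focus; with \code{null = TRUE} both
#' classes are drawn from the same (benign-style, isotropic) generative
#' parameters so that downstream discrimination is at chance.
#'
#' @param nBenign,nMalignant class sizes.
#' @param seed master seed; every random draw in the cohort flows from it.
#' @param null draw both classes from identical generative parameters.
#' @param readerJitterPx boundary jitter amplitude (px) for the two
#'   readers.
#' @param dim,spacing grid geometry passed to [phantomSpec()].
#' @param noiseSigma Rician noise level.
#' @return A list: \code{lesions} (per lesion: \code{series},
#'   \code{truth}, \code{annotations} list by reader, \code{label}) and
#'   \code{cohort} (data frame, one row per lesion x reader).
#' @export
generateCohort <- function(nBenign = 29, nMalignant = 34, seed = 1,
                           null = FALSE, readerJitterPx = c(1, 2),
                           dim = c(96, 96, 20),
                           spacing = c(1.25, 1.25, 2.5), noiseSigma = 15) {
  set.seed(seed)
  labels <- c(rep("benign", nBenign), rep("malignant", nMalignant))
  n <- length(labels)
  seeds <- sample.int(.Machine$integer.max - 1L, n + 2 * n)
  lesionSeeds <- seeds[seq_len(n)]
  readerSeeds <- matrix(seeds[n + seq_len(2 * n)], ncol = 2)

  centerMm <- dim * spacing / 2
  lesions <- vector("list", n)
  rows <- list()
  for (i in seq_len(n)) {
    lab <- labels[i]
    genLab <- if (null) "benign" else lab
    ax <- c(runif(2, 3, 9), runif(1, 3, 6))
    off <- runif(3, -1, 1) * c(5, 5, 2.5)
    base <- if (genLab == "malignant")
      rnorm(1, 0.9, 0.08) else rnorm(1, 1.6, 0.15)
    spec <- phantomSpec(
      dim = dim, spacing = spacing, label = lab,
      center = centerMm + off, semiAxes = ax,
      coreADCBase = max(base, if (genLab == "malignant") 0.6 else 1.2),
      dirMultipliers = if (genLab == "malignant")
        c(r = 1.0, p = 1.35, s = 0.75) else c(r = 1, p = 1, s = 1),
      rimADC = if (genLab == "malignant") 1.25 else 1.7,
      necroticFraction = if (genLab == "malignant")
        runif(1, 0.15, 0.5) else 0,
      noiseSigma = noiseSigma, seed = lesionSeeds[i])
    ph <- generatePhantom(spec)
    lid <- sprintf("L%03d", i)
    trueIdx <- which.max(apply(ph$truth, 3, sum))
    # a reader's boundary error cannot exceed the lesion's own scale:
    # cap the jitter at half the in-plane radius (in pixels)
    jcap <- 0.5 * min(ax[1:2]) / spacing[1]
    ann1 <- simulateReaderROI(ph$truth, jitterPx = min(readerJitterPx[1], jcap),
                              seed = readerSeeds[i, 1], lesionId = lid,
                              readerId = "R1", label = lab)
    ann2 <- simulateReaderROI(ph$truth, slices = trueIdx,
                              jitterPx = min(readerJitterPx[2], jcap),
                              seed = readerSeeds[i, 2], lesionId = lid,
                              readerId = "R2", label = lab)
    ph$series@lesionId <- lid
    lesions[[i]] <- list(series = ph$series, truth = ph$truth,
                         annotations = list(R1 = ann1, R2 = ann2),
                         label = lab)
    for (ann in list(ann1, ann2))
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = lid, reader_id = ann@readerId, label = lab,
        field_strength = "3.0T",
        roi_area_cm2 = maskArea(roiMask(ann), spacing[1:2], "cm2"),
        stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  validateCohort(cohort)
  list(lesions = lesions, cohort = cohort)
}
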