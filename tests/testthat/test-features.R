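test_that("voxel classification partitions the ROI at the 1.37 cutoff", {
  vals <- array(1.37, c(3, 3, 1))
  vals[1, 1, 1] <- 0
  vals[1:2, 2, 1] <- 1.0
  vals[3, 3, 1] <- 1.369
  adc <- new("ADCVolume", values = vals, direction = "r",
             spacing = c(1, 1, 1))
  roi <- matrix(TRUE, 3, 3)
  cls <- classifyVoxels(adc, roi, 1)
  # exactly-at-cutoff voxels are benign-like; 0 is cancer-like
  expect_false(cls$cancer[2, 1])
  expect_true(cls$cancer[1, 1])
  expect_equal(sum(cls$cancer), 4)
  expect_equal(sum(cls$benign), 5)
  expect_identical(cls$cancer | cls$benign, roi)
  expect_false(any(cls$cancer & cls$benign))

  # partition holds on random ROIs and values
  set.seed(5)
  for (i in 1:5) {
    v2 <- array(runif(16 * 16, 0, 3), c(16, 16, 1))
    a2 <- new("ADCVolume", values = v2, direction = "p", spacing = c(1, 1, 1))
    r2 <- randomMask(16, 16, 0.5, 3:14, 3:14)
    c2 <- classifyVoxels(a2, r2, 1)
    expect_identical(c2$cancer | c2$benign, r2)
    expect_equal(sum(c2$cancer & c2$benign), 0)
  }
})

test_that("SDAC applies the forced-zero rule and the sample SD", {
  expect_identical(computeSDAC(c(5, 6, 4)), 0)       # mean 5 < 6.67
  expect_equal(computeSDAC(c(10, 10, 10)), 0)        # zero variance
  expect_equal(computeSDAC(c(4, 8, 12)), 4)          # sample SD, n-1
  # equivalently: total below 20 mm^2 forces zero
  expect_identical(computeSDAC(c(6.6, 6.6, 6.6)), 0)
  expect_gt(computeSDAC(c(6.7, 6.7, 6.8)), 0)

  # permutation invariance and scale equivariance above the floor
  set.seed(9)
  for (i in 1:10) {
    x <- runif(3, 7, 40)
    expect_equal(computeSDAC(sample(x)), computeSDAC(x))
    expect_equal(computeSDAC(2.5 * x), 2.5 * computeSDAC(x))
  }
})

test_that("ACMB sums signed areas over directions", {
  expect_equal(computeACMB(c(10, 10, 10), c(2, 2, 2)), 24)
  expect_equal(computeACMB(c(0, 0, 0), c(5, 5, 5)), -15)
  expect_equal(computeACMB(numeric(3), numeric(3)), 0)
  # antisymmetric under swapping cancer and benign
  set.seed(2)
  a <- runif(3, 0, 50); b <- runif(3, 0, 50)
  expect_equal(computeACMB(a, b), -computeACMB(b, a))
})

test_that("baseline mean ADC averages directions then ROI voxels", {
  dims <- c(4, 4, 3)
  mk <- function(x) new("ADCVolume", values = array(x, dims), direction = "r",
                        spacing = c(1, 1, 1))
  adc <- list(r = mk(0.9), p = mk(1.2), s = mk(1.5))
  roi <- matrix(FALSE, 4, 4); roi[2, 2] <- TRUE
  ann <- LesionAnnotation("L", "R", "benign", list("2" = roi))
  expect_equal(meanADCBaseline(adc, ann), 1.2)

  # two ROI voxels with direction-averaged ADC 1.0 and 2.0 -> 1.5
  v <- array(1, dims); v[2, 2, 2] <- 1; v[3, 3, 2] <- 2
  one <- new("ADCVolume", values = v, direction = "r", spacing = c(1, 1, 1))
  roi2 <- matrix(FALSE, 4, 4); roi2[2, 2] <- TRUE; roi2[3, 3] <- TRUE
  ann2 <- LesionAnnotation("L", "R", "benign", list("2" = roi2))
  expect_equal(meanADCBaseline(list(r = one, p = one, s = one), ann2), 1.5)

  # multi-slice annotations pool all annotated ROI voxels
  roiA <- matrix(FALSE, 4, 4); roiA[1, 1] <- TRUE
  roiB <- matrix(FALSE, 4, 4); roiB[1, 1:2] <- TRUE
  v3 <- array(0, dims); v3[1, 1, 1] <- 1; v3[1, 1, 2] <- 2; v3[1, 2, 2] <- 3
  one3 <- new("ADCVolume", values = v3, direction = "r", spacing = c(1, 1, 1))
  ann3 <- LesionAnnotation("L", "R", "benign", list("1" = roiA, "2" = roiB))
  expect_equal(meanADCBaseline(list(r = one3, p = one3, s = one3), ann3), 2)
})

test_that("lesionFeatures ties the stages together on a phantom", {
  ph <- generatePhantom(phantomSpec(dim = c(48, 48, 10),
                                    center = c(30, 30, 12.5),
                                    semiAxes = c(6, 6, 4),
                                    noiseSigma = 10, seed = 77))
  ann <- simulateReaderROI(ph$truth, jitterPx = 1, seed = 8,
                           lesionId = "LX", readerId = "R1",
                           label = "malignant")
  lf <- lesionFeatures(ph$series, ann)
  f <- lf$features
  expect_equal(f$lesion_id, "LX")
  expect_gte(f$sdac, 0)
  expect_true(abs(f$acmb) <=
                3 * maskArea(roiMask(ann), c(1.25, 1.25)) + 1e-9)
  expect_gt(f$mean_jaccard, 0.5)
  expect_named(lf$subROIs, c("r", "p", "s"))
  # sub-ROIs partition the hand ROI in every direction
  for (d in c("r", "p", "s"))
    expect_identical(coreMask(lf$subROIs[[d]]) | periMask(lf$subROIs[[d]]),
                     roiMask(ann))
})
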