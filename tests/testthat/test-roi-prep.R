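test_that("contribution fractions match hand-enumerated overlaps", {
  # all-ones and empty-ish extremes
  hiAll <- HiResROI(matrix(TRUE, 8, 8), c(4, 4))
  expect_equal(contributionFractions(hiAll), matrix(1, 4, 4))

  # 4x4 -> 2x2 with the top-left 2x2 block set: fractions [[1,0],[0,0]]
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  fr <- contributionFractions(HiResROI(m, c(2, 2)))
  expect_equal(fr, matrix(c(1, 0, 0, 0), 2, 2))

  # non-integer ratio 3 -> 2: native cell 1 covers hi cells 1 and half of 2
  m2 <- matrix(FALSE, 3, 3); m2[1, 1] <- TRUE
  fr2 <- contributionFractions(HiResROI(m2, c(2, 2)))
  expect_equal(fr2[1, 1], (1 / 1.5)^2)  # (1 hi cell) / (1.5^2 footprint)
  expect_equal(fr2[2, 2], 0)
})

test_that("contribution fractions conserve physical ROI area", {
  set.seed(21)
  for (i in 1:10) {
    nh <- sample(10:40, 2); nn <- sample(4:9, 2)
    m <- matrix(runif(prod(nh)) < 0.3, nh[1], nh[2])
    if (!any(m)) m[1, 1] <- TRUE
    hi <- HiResROI(m, nn, pixelSpacing = c(1.25, 1.25))
    fr <- contributionFractions(hi)
    # sum(fractions) x native px area == hi count x hi px area, i.e.
    # sum(fr) == count x (nn1*nn2)/(nh1*nh2) after rescaling to one extent
    expect_equal(sum(fr), sum(m) * prod(nn) / prod(nh), tolerance = 1e-6)
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("majority down-sampling applies the >=50% rule inclusively", {
  # exactly 50%: two of four contributing hi pixels set -> included
  m <- matrix(FALSE, 4, 4); m[1, 1:2] <- TRUE  # half of native (1,1) block
  hi <- HiResROI(m, c(2, 2))
  expect_equal(contributionFractions(hi)[1, 1], 0.5)
  expect_true(downsampleMajority(hi)[1, 1])

  expect_equal(downsampleMajority(HiResROI(matrix(TRUE, 6, 6), c(3, 3))),
               matrix(TRUE, 3, 3))

  m2 <- matrix(FALSE, 4, 4); m2[1:2, 1:2] <- TRUE
  expect_equal(downsampleMajority(HiResROI(m2, c(2, 2))),
               matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))

  # a sliver below every native pixel's majority -> annotation lost
  m3 <- matrix(FALSE, 8, 8); m3[1, 1] <- TRUE
  expect_error(downsampleMajority(HiResROI(m3, c(2, 2))), "lost")

  # monotone in cutoff: higher cutoff never adds pixels
  set.seed(4)
  m4 <- matrix(runif(144) < 0.5, 12, 12)
  hi4 <- HiResROI(m4, c(4, 4))
  prev <- downsampleMajority(hi4, 0.05)
  for (co in c(0.25, 0.5, 0.75)) {
    cur <- contributionFractions(hi4) >= co
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("adaptive down-sampling matches a brute-force cutoff scan", {
  # constructed 8x8 -> 4x4 with fractions {0, 0.25, 0.75, 1}
  m <- matrix(FALSE, 8, 8)
  m[1:2, 1:2] <- TRUE                       # fraction 1 at native (1,1)
  m[1, 3] <- TRUE                           # fraction 0.25 at native (1,2)
  m[3:4, 3] <- TRUE; m[3, 4] <- TRUE        # fraction 0.75 at native (2,2)
  hi <- HiResROI(m, c(4, 4), pixelSpacing = c(10, 10),  # 1 px = 1 cm^2
                 recordedAreaCm2 = 2)       # = count(fraction >= 0.75)
  res <- downsampleAdaptive(hi)
  expect_equal(res$cutoff, 0.75)
  expect_equal(sum(res$mask), 2)

  # property: returned area error <= every candidate cutoff's error
  set.seed(31)
  for (i in 1:8) {
    mm <- matrix(runif(24 * 24) < 0.4, 24, 24)
    if (!any(mm)) mm[5, 5] <- TRUE
    rec <- runif(1, 0.2, 1.5)
    hi2 <- HiResROI(mm, c(6, 6), pixelSpacing = c(2.5, 2.5),
                    recordedAreaCm2 = rec)
    fr <- contributionFractions(hi2)
    res2 <- downsampleAdaptive(hi2)
    errs <- vapply(sort(unique(fr[fr > 0])), function(co)
      abs(sum(fr >= co) * 0.0625 - rec), 0)
    expect_lte(abs(maskArea(res2$mask, c(2.5, 2.5), "cm2") - rec),
               min(errs) + 1e-12)
  }

  # recorded area 0 with a non-empty mask: annotation lost
  hi0 <- HiResROI(matrix(TRUE, 4, 4), c(2, 2), recordedAreaCm2 = 0)
  expect_error(downsampleAdaptive(hi0), "lost")
  expect_error(downsampleAdaptive(HiResROI(matrix(TRUE, 4, 4), c(2, 2))),
               "recorded")
})

test_that("index-slice selection takes the largest ROI, ties low", {
  mk <- function(n) { m <- matrix(FALSE, 8, 8); m[seq_len(n), 1] <- TRUE; m }
  ann <- LesionAnnotation("L1", "R1", "benign",
                          list("3" = mk(4), "4" = mk(8), "5" = mk(6)))
  expect_equal(selectIndexSlice(ann), 4L)
  expect_equal(indexSlice(ann), 4L)

  ann2 <- LesionAnnotation("L1", "R1", "benign",
                           list("6" = mk(5), "2" = mk(5)))
  expect_equal(selectIndexSlice(ann2), 2L)

  ann3 <- LesionAnnotation("L1", "R1", "benign", list("7" = mk(3)))
  expect_equal(selectIndexSlice(ann3), 7L)

  # an explicit index slice that is not the largest ROI is invalid
  expect_error(LesionAnnotation("L1", "R1", "benign",
                                list("3" = mk(4), "4" = mk(8)),
                                indexSlice = 3), "largest")
})

test_that("cohort size filter drops lesions above 7.50 cm^2", {
  co <- data.frame(
    lesion_id = c("A", "A", "B", "B", "C"),
    reader_id = c("R1", "R2", "R1", "R2", "R1"),
    label = c("benign", "benign", "malignant", "malignant", "benign"),
    roi_area_cm2 = c(6.74, 6.9, 8.63, 7.2, 0.14),
    stringsAsFactors = FALSE)
  expect_message(out <- filterCohort(co), "excluding 1 lesion")
  expect_setequal(unique(out$lesion_id), c("A", "C"))  # 6.74 kept, 8.63 gone
  expect_equal(nrow(out), 3)

  empty <- co[0, ]
  expect_identical(filterCohort(empty), empty)
})
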