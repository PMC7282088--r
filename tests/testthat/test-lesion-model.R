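test_that("Jaccard index counts pixel overlap", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(jaccardIndex(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(jaccardIndex(a, b), 0)
  c_ <- matrix(FALSE, 4, 4); c_[2:3, 1:2] <- TRUE  # |a|=|b|=4, overlap 2
  expect_equal(jaccardIndex(a, c_), 2 / 6)
  expect_equal(jaccardIndex(a & FALSE, b & FALSE), 0)  # both empty
})

test_that("region growing reproduces the hand-worked 3x3 example", {
  # [[1,5,1],[5,5,1],[1,1,5]] (row-major), seed center, threshold 2:
  # under 8/26-connectivity the corner 5 touches the center diagonally
  v <- array(0, c(3, 3, 1))
  v[, , 1] <- matrix(c(1, 5, 1, 5, 5, 1, 1, 1, 5), 3, byrow = TRUE)
  au <- auVolume(v)
  g <- growVOI(au, c(2, 2, 1), 2, 26)
  got <- which(voiMask(g)[, , 1], arr.ind = TRUE)
  expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
               rbind(c(1, 2), c(2, 1), c(2, 2), c(3, 3)))

  # threshold below the global minimum on a positive volume: full grid
  vp <- array(runif(4 * 4 * 3, 1, 2), c(4, 4, 3))
  expect_true(all(voiMask(growVOI(auVolume(vp), c(2, 2, 2), 0.5))))
  # threshold at/above the seed value: empty
  g0 <- growVOI(auVolume(vp), c(2, 2, 2), vp[2, 2, 2])
  expect_false(any(voiMask(g0)))
  expect_false(g0@modeled)
  expect_error(growVOI(auVolume(vp), c(9, 1, 1), 0), "bounds")
})

test_that("grown components match the dilation-fixpoint oracle", {
  set.seed(42)
  for (i in 1:6) {
    v <- array(sample(0:9, 8 * 8 * 4, TRUE) + 0, c(8, 8, 4))
    seed <- c(sample(8, 1), sample(8, 1), sample(4, 1))
    thr <- sample(0:8, 1)
    conn <- sample(c(6, 18, 26), 1)
    g <- growVOI(auVolume(v), seed, thr, conn)
    expect_identical(voiMask(g), ccOracle(v, seed, thr, conn))
  }
})

test_that("VOIs nest under threshold increase and stay connected", {
  set.seed(7)
  v <- array(runif(12 * 12 * 6, 0, 10), c(12, 12, 6))
  au <- auVolume(v)
  seed <- c(6, 6, 3)
  thrs <- sort(runif(5, 0, v[6, 6, 3]))
  masks <- lapply(thrs, function(t) voiMask(growVOI(au, seed, t)))
  for (k in 2:length(masks))
    expect_true(all(masks[[k]] <= masks[[k - 1]]))  # VOI(t2) subset of VOI(t1)
  for (m in masks)
    expect_equal(nComponentsOracle(m), 1L)
})

test_that("a U-shaped lesion is 3D-connected but 2D-disconnected", {
  v <- array(0, c(9, 9, 3))
  # two vertical arms in slice 2, bridged through slice 1
  v[2:3, 2:7, 2] <- 10
  v[6:7, 2:7, 2] <- 10
  v[2:7, 2:3, 1] <- 10
  g <- growVOI(auVolume(v), c(2, 2, 2), 5, 26)
  cross <- voiMask(g)[, , 2]
  expect_equal(sum(cross), sum(v[, , 2] > 5))
  cross3d <- array(FALSE, c(9, 9, 1)); cross3d[, , 1] <- cross
  expect_equal(nComponentsOracle(cross3d), 2L)       # disconnected in-plane
  expect_equal(nComponentsOracle(voiMask(g)), 1L)    # connected in 3D
})

test_that("threshold selection equals an exhaustive brute-force scan", {
  set.seed(13)
  for (i in 1:10) {
    v <- array(sample(0:20, 16 * 16 * 5, TRUE) + runif(1), c(16, 16, 5))
    roi <- randomMask(16, 16, 0.5, 6:11, 6:11)
    roi[6, 6] <- roi[11, 11] <- TRUE  # pin the box so +5 dilation spans the grid
    au <- auVolume(v)
    sel <- selectThreshold(au, roi, 3)
    seed <- sel$seed
    expect_true(roi[seed[1], seed[2]])
    lin <- seed[1] + 16 * ((seed[2] - 1) + 16 * (seed[3] - 1))
    uv <- sort(unique(as.numeric(v)))
    jb <- vapply(c(uv[1] - 0.5, uv), function(t) {
      comp <- ccOracle(v, seed, t, 26)
      jaccardIndex(comp[, , 3], roi)
    }, 0)
    expect_equal(sel$jaccard, max(jb), tolerance = 1e-12)
    # returned VOI's own cross-section reproduces the reported Jaccard
    expect_equal(jaccardIndex(voiMask(sel$voi)[, , 3], roi), sel$jaccard)
  }
})

test_that("threshold selection recovers an extruded indicator exactly", {
  roi <- matrix(FALSE, 10, 10); roi[3:7, 4:8] <- TRUE
  v <- array(0, c(10, 10, 5))
  for (k in 2:4) v[, , k] <- roi * 7
  sel <- selectThreshold(auVolume(v), roi, 3)
  expect_equal(sel$jaccard, 1)
  expect_equal(voiMask(sel$voi)[, , 3], roi)

  # spatially constant volume: lowest candidate gives |ROI|/|slice|
  vc <- array(5, c(10, 10, 4))
  selc <- selectThreshold(auVolume(vc), roi, 2)
  expect_equal(selc$jaccard, sum(roi) / (10 * 10))
})

test_that("core/peri split partitions the hand ROI", {
  roi <- matrix(FALSE, 8, 8); roi[2:6, 2:3] <- TRUE  # 10 px
  v <- array(0, c(8, 8, 3))
  v[2:4, 2:3, 2] <- 9  # model covers 6 of the 10 ROI px
  voi <- growVOI(auVolume(v), c(2, 2, 2), 5)
  pair <- splitCorePeri(voi, roi, 2)
  expect_equal(sum(coreMask(pair)), 6)
  expect_equal(sum(periMask(pair)), 4)
  expect_identical(coreMask(pair) | periMask(pair), roi)
  expect_false(any(coreMask(pair) & periMask(pair)))

  # cross-section covering the ROI: peri empty; disjoint: core empty
  vAll <- array(9, c(8, 8, 3))
  pairAll <- splitCorePeri(growVOI(auVolume(vAll), c(1, 1, 2), 5), roi, 2)
  expect_identical(coreMask(pairAll), roi)
  expect_false(any(periMask(pairAll)))
  vNone <- array(0, c(8, 8, 3)); vNone[8, 8, 2] <- 9
  pairNone <- splitCorePeri(growVOI(auVolume(vNone), c(8, 8, 2), 5), roi, 2)
  expect_false(any(coreMask(pairNone)))
  expect_identical(periMask(pairNone), roi)
})
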