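test_that("binormal ROC matches closed-form and Monte-Carlo values", {
  # identical class distributions: a=0, b=1 -> AUC 0.5, sens 0.10 at spec 0.90
  set.seed(100)
  roc0 <- fitBinormal(rnorm(2000), rep(c("benign", "malignant"), 1000))
  expect_equal(roc0@auc, pnorm(roc0@a / sqrt(1 + roc0@b^2)))
  expect_equal(roc0@auc, 0.5, tolerance = 0.05)

  # constructed a=1.19, b=1 -> AUC = pnorm(1.19/sqrt(2)) ~ 0.800
  n <- 2e5
  neg <- rnorm(n, 0, 1); pos <- rnorm(n, 1.19, 1)
  roc <- fitBinormal(c(neg, pos), rep(c("benign", "malignant"), each = n))
  expect_equal(roc@a, 1.19, tolerance = 0.02)
  expect_equal(roc@b, 1, tolerance = 0.02)
  expect_equal(pnorm(1.19 / sqrt(2)), 0.8, tolerance = 0.001)
  # Monte-Carlo empirical AUC agrees with the closed form within 0.005
  expect_equal(roc@aucEmpirical, roc@auc, tolerance = 0.005)

  # sensitivity at fixed specificity on the binormal curve
  mk <- function(a, b) new("ROCResult", a = a, b = b,
    auc = pnorm(a / sqrt(1 + b^2)), aucEmpirical = 0.5,
    sensAtSpec = c("0.9" = 0), scores = c(0, 1, 0, 1),
    labels = rep(c("benign", "malignant"), 2), nPos = 2L, nNeg = 2L,
    method = "binormal")
  expect_equal(sensitivityAtSpecificity(mk(0, 1), 0.90), 0.10)
  expect_equal(sensitivityAtSpecificity(mk(1, 1), 0.90),
               pnorm(1 + qnorm(0.1)), tolerance = 1e-12)
  expect_equal(pnorm(1 + qnorm(0.1)), 0.389, tolerance = 0.001)
  expect_gt(sensitivityAtSpecificity(mk(50, 1), 0.99), 0.9999)

  # curve endpoints: TPF(0)=0, TPF(1)=1
  expect_equal(pnorm(roc@a + roc@b * qnorm(0)), 0)
  expect_equal(pnorm(roc@a + roc@b * qnorm(1)), 1)
})

test_that("empirical AUC is invariant under monotone score transforms", {
  set.seed(17)
  scores <- rnorm(60)
  labels <- rep(c("benign", "malignant"), 30)
  base <- empiricalAUC(scores, labels)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
    expect_equal(empiricalAUC(f(scores), labels), base)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                          levels = c("benign", "malignant"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(base, ref)
  }
})

test_that("degenerate scores fall back to the empirical ROC", {
  scores <- c(rep(1, 10), rep(2, 10))
  labels <- rep(c("benign", "malignant"), each = 10)
  expect_warning(roc <- fitBinormal(scores, labels), "zero within-class")
  expect_equal(roc@method, "empirical")
  expect_equal(roc@auc, 1)
})

test_that("cross-validated MBC behaves on separable, null and constant data", {
  set.seed(23)
  n <- 30
  feats <- data.frame(
    sdac = c(rnorm(n, 2, 0.5), rnorm(n, 20, 0.5)),  # wide margin
    acmb = rnorm(2 * n),
    label = rep(c("benign", "malignant"), each = n))
  sc <- suppressWarnings(fitMBC(feats, cvConfig(seed = 3)))
  expect_equal(empiricalAUC(sc, feats$label), 1)

  # identical seed -> identical scores
  sc2 <- suppressWarnings(fitMBC(feats, cvConfig(seed = 3)))
  expect_identical(sc, sc2)

  # permuted labels carry no signal: chance-level AUC on average (single
  # permutations are noisy — cross-validated scores correlate through the
  # shared training folds — so the check averages ten permutations)
  set.seed(31)
  aucsNull <- vapply(1:10, function(s) {
    featsNull <- data.frame(sdac = rnorm(60), acmb = rnorm(60),
                            label = sample(rep(c("benign", "malignant"), 30)))
    scNull <- suppressWarnings(fitMBC(featsNull,
                                      cvConfig(nRepeats = 20, seed = s)))
    empiricalAUC(scNull, featsNull$label)
  }, 0)
  expect_lt(abs(mean(aucsNull) - 0.5), 0.15)

  # constant features: all scores equal, AUC 0.5
  featsC <- data.frame(sdac = rep(1, 40), acmb = rep(2, 40),
                       label = rep(c("benign", "malignant"), 20))
  scC <- suppressWarnings(fitMBC(featsC, cvConfig(seed = 7)))
  expect_lt(diff(range(scC)), 1e-9)
  expect_equal(empiricalAUC(scC, featsC$label), 0.5)

  expect_error(fitMBC(feats[c(1, 2, n + 1), ], cvConfig()), ">= 2 lesions")
})

test_that("evaluatePipeline reports all four classifiers per reader", {
  set.seed(41)
  n <- 24
  mkReader <- function(rid) data.frame(
    lesion_id = sprintf("L%02d", 1:n), reader_id = rid,
    label = rep(c("benign", "malignant"), each = n / 2),
    sdac = c(rnorm(n / 2, 1, 1), rnorm(n / 2, 6, 2)),
    acmb = c(rnorm(n / 2, -10, 5), rnorm(n / 2, 15, 5)),
    mean_adc = c(rnorm(n / 2, 1.6, 0.2), rnorm(n / 2, 1.1, 0.2)),
    roi_area_cm2 = rep(c(0.5, 2), n / 2), stringsAsFactors = FALSE)
  feats <- rbind(mkReader("R1"), mkReader("R2"))
  ev <- suppressWarnings(evaluatePipeline(feats, cvConfig(nRepeats = 5,
                                                          seed = 2)))
  expect_setequal(ev$summary$feature, c("baseline", "sdac", "acmb", "mbc"))
  expect_setequal(ev$summary$reader_id, c("R1", "R2"))
  expect_true(all(ev$summary$auc >= 0 & ev$summary$auc <= 1))
  expect_true(all(ev$summary$auc > 0.5))  # all features point the right way

  # subgroup filter restricts rows
  evS <- suppressWarnings(
    evaluatePipeline(feats, cvConfig(nRepeats = 5, seed = 2),
                     subgroup = function(df) df$roi_area_cm2 < 1))
  expect_true(all(evS$summary$n < n))

  # ACMB constant: MBC falls back to the SDAC signal alone
  featsC <- mkReader("R1"); featsC$acmb <- 5
  evC <- suppressWarnings(evaluatePipeline(featsC,
                                           cvConfig(nRepeats = 5, seed = 2)))
  s <- evC$summary
  expect_equal(s$auc_empirical[s$feature == "mbc"],
               s$auc_empirical[s$feature == "sdac"], tolerance = 0.05)
})
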