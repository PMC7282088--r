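#' @include AllClasses.R
NULL

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{DSC(A, B) = 2|A \cap B| / (|A| + |B|)}; defined as 0 when both
#' masks are empty. Related to the Jaccard index by
#' \eqn{DSC = 2J/(1+J)}. A DSC above 0.8 is read as substantial
#' agreement.
#'
#' @param a,b logical masks of identical shape.
#' @return Fraction in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}

#' Wilcoxon signed-rank test on paired values
#'
#' Two-sided test on the paired differences (or on a single vector of
#' differences). Zero differences are dropped. The exact null
#' distribution is used for up to 25 non-zero untied differences;
#' otherwise the normal approximation with continuity correction. With no
#' non-zero differences the p-value is 1.
#'
#' @param x numeric vector (differences, or first member of each pair).
#' @param y optional second member of each pair.
#' @return Two-sided p-value.
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  exact <- n <= 25 && !anyDuplicated(abs(d))
  suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)$p.value)
}

#' McNemar test on paired binary indicators
#'
#' Compares paired proportions (e.g. the fraction of lesions with
#' substantial agreement under two ROI definitions). With up to 25
#' discordant pairs the exact binomial test on the discordant split is
#' used; beyond that, the chi-square test with continuity correction.
#' With no discordant pairs the p-value is 1.
#'
#' @param a,b paired logical vectors.
#' @return Two-sided p-value.
#' @export
mcnemarTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  nd <- n10 + n01
  if (nd == 0) return(1)
  if (nd <= 25) return(binom.test(n10, nd, 0.5)$p.value)
  tab <- matrix(c(sum(a & b), n01, n10, sum(!a & !b)), 2)
  mcnemar.test(tab, correct = TRUE)$p.value
}

#' Two-sided t-test on benign vs malignant ROI sizes
#'
#' Welch two-sample t-test (unequal variances) comparing hand-drawn ROI
#' areas between classes. Degenerate identical constant groups return
#' p = 1.
#'
#' @param areasBenign,areasMalignant numeric vectors of ROI areas.
#' @return Two-sided p-value.
#' @export
roiSizeTTest <- function(areasBenign, areasMalignant) {
  if (sd(areasBenign) == 0 && sd(areasMalignant) == 0)
    return(if (mean(areasBenign) == mean(areasMalignant)) 1 else 0)
  t.test(areasBenign, areasMalignant)$p.value
}

#' Inter-observer agreement analysis
#'
#' For each lesion, computes the Dice coefficient between the two
#' readers' hand-drawn index-slice ROIs and the mean Dice over the three
#' directional algorithm-generated lesion-core sub-ROIs, flags
#' substantial agreement (DSC > 0.8) for both, and runs the paired
#' Wilcoxon signed-rank test (hand vs core DSC), the McNemar test on the
#' substantial-agreement indicators, and the benign-vs-malignant ROI size
#' t-test. When the readers chose different index slices the masks are
#' compared in-plane on Reader 1's index slice.
#'
#' @param perLesion list with one element per lesion, each a list with
#'   \code{hand1}, \code{hand2} (logical index-slice masks),
#'   \code{core1}, \code{core2} (named lists of per-direction core
#'   masks), \code{label}, and \code{area_mm2} (Reader 1 hand-ROI area).
#' @return A list: \code{perLesion} data frame (lesion DSCs and
#'   indicators), \code{meanDSCHand}, \code{meanDSCCore},
#'   \code{propSubstantialHand}, \code{propSubstantialCore},
#'   \code{pWilcoxon}, \code{pMcNemar}, \code{pSizeTTest}.
#' @export
agreementAnalysis <- function(perLesion) {
  rows <- lapply(perLesion, function(les) {
    dscHand <- diceCoefficient(les$hand1, les$hand2)
    dscCore <- mean(vapply(names(les$core1), function(d)
      diceCoefficient(les$core1[[d]], les$core2[[d]]), 0))
    data.frame(lesion_id = les$lesion_id, label = les$label,
               dsc_hand = dscHand, dsc_core = dscCore,
               substantial_hand = dscHand > 0.8,
               substantial_core = dscCore > 0.8,
               area_mm2 = les$area_mm2, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ben <- df$label == "benign"
  list(perLesion = df,
       meanDSCHand = mean(df$dsc_hand),
       meanDSCCore = mean(df$dsc_core),
       propSubstantialHand = mean(df$substantial_hand),
       propSubstantialCore = mean(df$substantial_core),
       pWilcoxon = wilcoxonSignedRank(df$dsc_core, df$dsc_hand),
       pMcNemar = mcnemarTest(df$substantial_core, df$substantial_hand),
       pSizeTTest = if (any(ben) && any(!ben))
         roiSizeTTest(df$area_mm2[ben], df$area_mm2[!ben]) else NA_real_)
}
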