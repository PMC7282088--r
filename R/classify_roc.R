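#' @include AllClasses.R
NULL

#' Cross-validation configuration
#'
#' @param nFolds number of folds (>= 2), default 5.
#' @param nRepeats number of repeated fold draws, default 20 (stabilizes
#'   fold noise at cohort sizes around 60).
#' @param stratified draw folds stratified by class, default TRUE.
#' @param seed RNG seed driving all fold draws.
#' @return A list of class \code{"CVConfig"}.
#' @export
cvConfig <- function(nFolds = 5, nRepeats = 20, stratified = TRUE, seed = 1) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  structure(list(nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "CVConfig")
}

## stratified fold assignment; every fold must contain both classes
.drawFolds <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

.foldsValid <- function(y, fold, k) {
  all(vapply(seq_len(k), function(f) {
    length(unique(y[fold == f])) == 2L && sum(fold != f & y) >= 1 &&
      sum(fold != f & !y) >= 1
  }, TRUE))
}

#' Empirical (rank-based) AUC
#'
#' Mann-Whitney estimate of the probability that a malignant lesion
#' scores above a benign one, with ties counted half.
#'
#' @param scores numeric classifier scores (larger = more malignant).
#' @param labels \code{"benign"}/\code{"malignant"} (or logical, TRUE =
#'   malignant).
#' @return AUC in [0, 1].
#' @export
empiricalAUC <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == "malignant"
  nPos <- as.numeric(sum(y)); nNeg <- as.numeric(sum(!y))
  if (nPos == 0 || nNeg == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Fit the model-based classifier (MBC) with repeated cross-validation
#'
#' Combines SDAC and ACMB into a single malignancy score by logistic
#' regression with repeated stratified k-fold cross-validation: in each
#' repeat the model is fit on the training folds and each lesion receives
#' its out-of-fold predicted probability; the final score is the mean over
#' repeats. If a fold draw leaves a fold without both classes it is
#' redrawn (up to 100 attempts). Complete separation in a training fold
#' triggers a ridge-penalized refit (penalty 1e-6) with a warning.
#'
#' @param features data frame with columns \code{sdac}, \code{acmb} and
#'   \code{label}.
#' @param cv a [cvConfig()] object.
#' @return Numeric vector of cross-validated malignancy scores, one per
#'   row of \code{features}.
#' @export
fitMBC <- function(features, cv = cvConfig()) {
  y <- features$label == "malignant"
  if (sum(y) < 2 || sum(!y) < 2) stop("need >= 2 lesions per class")
  X <- as.matrix(features[, c("sdac", "acmb")])
  set.seed(cv$seed)
  scores <- matrix(NA_real_, nrow(features), cv$nRepeats)
  for (rep_ in seq_len(cv$nRepeats)) {
    fold <- .drawFolds(y, cv$nFolds, cv$stratified)
    tries <- 1L
    while (!.foldsValid(y, fold, cv$nFolds)) {
      if (tries >= 100L)
        stop("could not draw folds containing both classes; ",
             "reduce nFolds below the smaller class size")
      fold <- .drawFolds(y, cv$nFolds, cv$stratified)
      tries <- tries + 1L
    }
    for (f in seq_len(cv$nFolds)) {
      tr <- fold != f
      dtr <- data.frame(y = y[tr], sdac = X[tr, 1], acmb = X[tr, 2])
      dte <- data.frame(sdac = X[!tr, 1], acmb = X[!tr, 2])
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(y ~ sdac + acmb, family = binomial(), data = dtr),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
            sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (sep && requireNamespace("glmnet", quietly = TRUE)) {
        warning("separation in training fold; refit with ridge penalty 1e-6")
        gfit <- glmnet::glmnet(cbind(dtr$sdac, dtr$acmb), factor(dtr$y),
                               family = "binomial", alpha = 0, lambda = 1e-6)
        p <- as.numeric(predict(gfit, cbind(dte$sdac, dte$acmb),
                                type = "response"))
      } else {
        p <- predict(fit, dte, type = "response")
      }
      scores[!tr, rep_] <- p
    }
  }
  # snap sub-tolerance float noise so identical lesions score identically
  # (IRLS returns probabilities matching only to ~1 ulp across folds)
  round(rowMeans(scores), 12)
}

#' Fit a binormal ROC curve by Gaussian moment matching
#'
#' Estimates the per-class mean and standard deviation of the scores and
#' forms the binormal parameters \eqn{a = (\mu_+ - \mu_-)/\sigma_+},
#' \eqn{b = \sigma_-/\sigma_+}; the fitted curve is
#' \eqn{TPF(FPF) = \Phi(a + b\,\Phi^{-1}(FPF))} with
#' \eqn{AUC = \Phi(a/\sqrt{1+b^2})}. The rank-based empirical AUC is
#' always reported alongside. When either within-class standard deviation
#' is zero the binormal model is undefined: the fit falls back to the
#' empirical ROC with a warning.
#'
#' @param scores numeric classifier scores (larger = more malignant).
#' @param labels \code{"benign"}/\code{"malignant"} or logical.
#' @param specificities specificities at which sensitivity is read,
#'   default 0.90.
#' @return A [ROCResult-class].
#' @export
fitBinormal <- function(scores, labels, specificities = 0.90) {
  y <- if (is.logical(labels)) labels else labels == "malignant"
  labs <- ifelse(y, "malignant", "benign")
  pos <- scores[y]; neg <- scores[!y]
  if (length(pos) < 2 || length(neg) < 2) stop("need >= 2 scores per class")
  aucEmp <- empiricalAUC(scores, y)
  sdP <- sd(pos); sdN <- sd(neg)
  if (sdP < .Machine$double.eps^0.5 || sdN < .Machine$double.eps^0.5) {
    warning("zero within-class standard deviation; falling back to empirical ROC")
    sens <- vapply(specificities, function(sp)
      .empiricalSensAtSpec(scores, y, sp), 0)
    return(new("ROCResult", a = NA_real_, b = NA_real_, auc = aucEmp,
               aucEmpirical = aucEmp,
               sensAtSpec = structure(sens, names = as.character(specificities)),
               scores = as.numeric(scores), labels = labs,
               nPos = length(pos), nNeg = length(neg), method = "empirical"))
  }
  a <- (mean(pos) - mean(neg)) / sdP
  b <- sdN / sdP
  auc <- pnorm(a / sqrt(1 + b^2))
  sens <- pnorm(a + b * qnorm(1 - specificities))
  new("ROCResult", a = a, b = b, auc = auc, aucEmpirical = aucEmp,
      sensAtSpec = structure(sens, names = as.character(specificities)),
      scores = as.numeric(scores), labels = labs,
      nPos = length(pos), nNeg = length(neg), method = "binormal")
}

.empiricalSensAtSpec <- function(scores, y, spec) {
  fpfTarget <- 1 - spec
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- 0
  for (t in thr) {
    fpf <- mean(scores[!y] >= t)
    if (fpf > fpfTarget) break
    sens <- mean(scores[y] >= t)
  }
  sens
}

#' Sensitivity at a fixed specificity on a fitted ROC curve
#'
#' Reads the true-positive fraction at a false-positive fraction of
#' \code{1 - specificity} on the binormal curve,
#' \eqn{\Phi(a + b\,\Phi^{-1}(1 - spec))}; for an empirical fallback fit
#' the empirical step curve is used.
#'
#' @param roc a [ROCResult-class].
#' @param specificity target specificity, default 0.90.
#' @return Sensitivity in [0, 1].
#' @export
sensitivityAtSpecificity <- function(roc, specificity = 0.90) {
  if (roc@method == "binormal")
    pnorm(roc@a + roc@b * qnorm(1 - specificity))
  else
    .empiricalSensAtSpec(roc@scores, roc@labels == "malignant", specificity)
}

#' Evaluate all classifiers on a feature table
#'
#' Fits ROC curves per reader for the baseline (mean ADC, entered negated
#' so larger = more malignant), SDAC alone, ACMB alone, and the combined
#' cross-validated model-based classifier (MBC). An optional subgroup
#' predicate restricts the cohort (e.g. lesions under 1 cm^2, masses
#' only, one field strength).
#'
#' @param features feature table from [lesionFeatures()] rows (one row
#'   per lesion x reader).
#' @param cv a [cvConfig()] for the MBC fit.
#' @param specificities specificities at which sensitivity is reported.
#' @param subgroup optional function taking the feature table and
#'   returning a logical row filter.
#' @return A list with \code{summary} (data frame: reader, feature,
#'   auc, auc_empirical, sens_at_spec) and \code{roc} (nested list of
#'   [ROCResult-class] by reader and feature).
#' @export
evaluatePipeline <- function(features, cv = cvConfig(), specificities = 0.90,
                             subgroup = NULL) {
  if (!is.null(subgroup)) features <- features[subgroup(features), , drop = FALSE]
  out <- list(); rows <- list()
  for (rd in sort(unique(features$reader_id))) {
    fr <- features[features$reader_id == rd, , drop = FALSE]
    scoreSets <- list(
      baseline = -fr$mean_adc,   # low ADC orients toward malignancy
      sdac     = fr$sdac,
      acmb     = fr$acmb,
      mbc      = fitMBC(fr, cv))
    out[[rd]] <- lapply(scoreSets, fitBinormal, labels = fr$label,
                        specificities = specificities)
    for (feat in names(scoreSets)) {
      roc <- out[[rd]][[feat]]
      rows[[length(rows) + 1L]] <- data.frame(
        reader_id = rd, feature = feat, n = nrow(fr),
        auc = roc@auc, auc_empirical = roc@aucEmpirical,
        sens_at_spec = roc@sensAtSpec[1], stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       roc = out)
}
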