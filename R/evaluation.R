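## Evaluation suite: confusion-matrix metrics, ROC/AUC by threshold sweep
## (trapezoid rule, equal to the Mann-Whitney rank statistic under ties),
## and DeLong's paired test for correlated AUCs via placement values.

.checkLabels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be represented in the labels")
  labels
}

#' Confusion counts
#'
#' @param labels 0/1 truth vector.
#' @param predictions 0/1 (or `"yes"`/`"no"`) prediction vector of the
#'   same length.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(labels, predictions) {
  if (is.character(predictions))
    predictions <- as.integer(predictions == "yes")
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  c(TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Threshold metrics from a confusion matrix
#'
#' Computes sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' accuracy, Matthews correlation coefficient, precision
#' `P = TP/(TP+FP)` and `F1 = 2PR/(P+R)` (recall R = Sn). Zero
#' denominators follow the documented conventions: MCC, precision and F1
#' are 0 when undefined.
#'
#' @param labels 0/1 truth vector with both classes present.
#' @param predictions 0/1 or `"yes"`/`"no"` predictions.
#' @return Named list with `Sn`, `Sp`, `Acc`, `MCC`, `Precision`, `F1`
#'   and the four counts.
#' @export
confusionMetrics <- function(labels, predictions) {
  labels <- .checkLabels(labels)
  cc <- confusionCounts(labels, predictions)
  TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  sn <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  acc <- (TP + TN) / (TP + FP + TN + FN)
  mccDen <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mccDen == 0) 0 else (TP * TN - FP * FN) / mccDen
  prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f1 <- if (prec + sn == 0) 0 else 2 * prec * sn / (prec + sn)
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc, Precision = prec, F1 = f1,
       TP = TP, FP = FP, TN = TN, FN = FN)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score (plus infinite endpoints) as a threshold,
#' recording sensitivity and 1 - specificity, and integrates by the
#' trapezoid rule. With tied scores this equals the Mann-Whitney rank
#' statistic (concordant pairs plus half ties over positive x negative
#' pairs).
#'
#' @param labels 0/1 truth vector with both classes present.
#' @param scores Finite numeric scores, higher = more positive.
#' @return A list with `points` (data frame `threshold`, `Sn`, `Sp`,
#'   `FPR`) and `auc`.
#' @export
rocCurve <- function(labels, scores) {
  labels <- .checkLabels(labels)
  if (length(scores) != length(labels))
    stop("labels and scores must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nNeg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, Sn = tpr, Sp = 1 - fpr,
                           FPR = fpr),
       auc = auc)
}

#' @rdname rocCurve
#' @return `rocAuc`: the AUC as a single number.
#' @export
rocAuc <- function(labels, scores) rocCurve(labels, scores)$auc

## Placement values: for each positive, the fraction of negatives it
## outranks (ties count 1/2); and symmetrically for negatives.
.placements <- function(pos, neg) {
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp))
}

#' DeLong's paired test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same labeled samples
#' using the DeLong placement-value covariance estimate and a two-sided
#' normal reference. Identical score vectors (zero variance of the AUC
#' difference) return p = 1 by convention.
#'
#' @param labels 0/1 truth vector with both classes present.
#' @param scoresA,scoresB Two score vectors over the same samples.
#' @return A list with `aucA`, `aucB`, `z` and `p`.
#' @export
delongTest <- function(labels, scoresA, scoresB) {
  labels <- .checkLabels(labels)
  if (length(scoresA) != length(labels) ||
      length(scoresB) != length(labels))
    stop("labels and both score vectors must have equal length")
  pos <- labels == 1L
  pA <- .placements(scoresA[pos], scoresA[!pos])
  pB <- .placements(scoresB[pos], scoresB[!pos])
  aucA <- mean(pA$v10)
  aucB <- mean(pB$v10)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  ## covariance of the placement values between the two score vectors
  s10 <- stats::cov(cbind(pA$v10, pB$v10))
  s01 <- stats::cov(cbind(pA$v01, pB$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(varDiff) || varDiff <= 0) {
    return(list(aucA = aucA, aucB = aucB, z = 0, p = 1))
  }
  z <- (aucA - aucB) / sqrt(varDiff)
  list(aucA = aucA, aucB = aucB, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Stratified train/test split helper
#'
#' @param labels 0/1 vector.
#' @param testFraction Fraction of each class assigned to the test split.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, testFraction = 0.25, seed = NULL) {
  stopifnot(testFraction > 0, testFraction < 1)
  labels <- as.integer(labels)
  withSeed(seed, {
    test <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(length(idx) * testFraction)))
    }))
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Plot a ROC curve
#'
#' Thin ggplot2 wrapper around the `points` component of [rocCurve()].
#'
#' @param roc A list as returned by [rocCurve()].
#' @return A ggplot object.
#' @export
plotRoc <- function(roc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(roc$points, ggplot2::aes(x = FPR, y = Sn)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::labs(x = "1 - Sp", y = "Sn",
                  subtitle = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}
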