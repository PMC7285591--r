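## SMOTE minority oversampling. Applied to the training partition only:
## the pipeline never exposes it on test data, and synthetic rows carry a
## provenance flag that the evaluation functions refuse.

#' SMOTE: synthetic minority oversampling
#'
#' Raises the minority class to `targetCount` rows by interpolating
#' between real minority samples: each synthetic row is
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of the
#' `kNeighbors` nearest minority neighbors of `x` (Euclidean distance on
#' the raw feature scale; neighbor distance ties broken by row index).
#' Real rows pass through bitwise untouched and synthetic rows are flagged
#' `"synthetic"` in the provenance.
#'
#' @param dataset A [LabeledDataset-class].
#' @param kNeighbors Number of nearest minority neighbors to draw from
#'   (default 5, capped at minority size - 1).
#' @param targetCount Desired minority row count after oversampling;
#'   default balances fully to the majority count.
#' @param seed Integer seed for reproducibility (restores the caller's RNG
#'   state afterwards).
#' @return A new [LabeledDataset-class] with `targetCount` minority rows.
#' @export
smote <- function(dataset, kNeighbors = 5, targetCount = NULL, seed = NULL) {
  stopifnot(is(dataset, "LabeledDataset"), kNeighbors >= 1)
  X <- featureMatrix(dataset)
  y <- sampleLabels(dataset)
  counts <- c(`0` = sum(y == 0L), `1` = sum(y == 1L))
  minorityLabel <- if (counts["1"] <= counts["0"]) 1L else 0L
  minIdx <- which(y == minorityLabel)
  nMin <- length(minIdx)
  if (nMin < 2L) stop("minority class must have at least 2 samples")
  if (is.null(targetCount)) targetCount <- max(counts)
  if (targetCount < nMin)
    stop("targetCount is below the current minority count")
  nNew <- targetCount - nMin
  if (nNew == 0L) return(dataset)

  Xmin <- X[minIdx, , drop = FALSE]
  k <- min(kNeighbors, nMin - 1L)
  D <- as.matrix(dist(Xmin))
  ## k nearest neighbors per minority row, excluding self, ties by index
  nn <- t(vapply(seq_len(nMin), function(i) {
    ord <- order(D[i, -i])  # stable: order() breaks ties by position
    cand <- seq_len(nMin)[-i][ord]
    cand[seq_len(k)]
  }, integer(k)))
  if (k == 1L) nn <- matrix(nn, ncol = 1L)

  synth <- withSeed(seed, {
    base <- sample(seq_len(nMin), nNew, replace = TRUE)
    pick <- sample(seq_len(k), nNew, replace = TRUE)
    u <- runif(nNew)
    Xb <- Xmin[base, , drop = FALSE]
    Xn <- Xmin[nn[cbind(base, pick)], , drop = FALSE]
    Xb + u * (Xn - Xb)
  })
  rownames(synth) <- if (is.null(rownames(X))) NULL
                     else sprintf("smote_%d", seq_len(nNew))

  labeledDataset(
    features = rbind(X, synth),
    labels = c(y, rep(minorityLabel, nNew)),
    provenance = c(sampleProvenance(dataset), rep("synthetic", nNew))
  )
}
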