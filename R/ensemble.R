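## The core classifier: a discrete AdaBoost loop whose weak learners are
## random forests. Base forests are made weight-aware by training on
## bootstrap draws sampled proportionally to the boosting weights, which
## keeps the contract independent of any particular forest library.

ALPHA_MAX <- log(1e10)

#' Boosting parameters
#'
#' Defaults follow the method's published operating point: forests of 10
#' trees with maximum depth 150, 300 boosting rounds, learning rate 0.75.
#'
#' @param nTrees Trees per base forest.
#' @param maxDepth Maximum tree depth.
#' @param rounds Boosting rounds T.
#' @param learningRate Multiplier applied to every learner weight.
#' @return A list of class `boostParams`.
#' @export
boostParams <- function(nTrees = 10, maxDepth = 150, rounds = 300,
                        learningRate = 0.75) {
  stopifnot(nTrees >= 1, rounds >= 1, learningRate > 0)
  structure(list(nTrees = nTrees, maxDepth = maxDepth, rounds = rounds,
                 learningRate = learningRate), class = "boostParams")
}

.fitBaseForest <- function(X, y, w, params, seed) {
  n <- nrow(X)
  idx <- sample(n, n, replace = TRUE, prob = w)
  df <- as.data.frame(X[idx, , drop = FALSE])
  df$.y <- factor(y[idx], levels = c(0L, 1L))
  if (nlevels(droplevels(df$.y)) < 2L) {
    ## degenerate bootstrap draw: force one sample of the missing class
    missing <- setdiff(c(0L, 1L), unique(y[idx]))
    swap <- which(y == missing)[1L]
    df[1L, seq_len(ncol(X))] <- X[swap, ]
    df$.y[1L] <- factor(missing, levels = c(0L, 1L))
  }
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = params$nTrees, max.depth = params$maxDepth,
    probability = TRUE, seed = seed, num.threads = 1L
  )
}

.baseProb <- function(forest, X) {
  p <- predict(forest, data = as.data.frame(X),
               num.threads = 1L)$predictions
  p[, "1"]
}

#' Fit the boosted random-forest classifier
#'
#' Discrete AdaBoost: sample weights start uniform; each round fits a
#' weight-aware random forest, computes its weighted training error
#' \eqn{\varepsilon_t}, sets
#' \eqn{\alpha_t = \eta \cdot \tfrac12 \ln\frac{1-\varepsilon_t}{\varepsilon_t}}
#' (learning rate \eqn{\eta} outside the log term), multiplies the weights
#' of misclassified samples by \eqn{e^{\alpha_t}} and renormalizes. The
#' loop stops early when \eqn{\varepsilon_t = 0} (weight capped at
#' `ln 1e10`) or \eqn{\varepsilon_t \ge 0.5} (round retained with weight
#' clamped at 0); previously fitted rounds are always retained.
#'
#' @param dataset A [LabeledDataset-class] (or anything accepted by
#'   [labeledDataset()] via `features`/`labels` arguments).
#' @param params A [boostParams()] list.
#' @param threshold Decision threshold stored with the model (default
#'   0.44, the pair-prediction operating point; use 0.48 for aptamer
#'   prediction).
#' @param seed Integer seed controlling the bootstrap draws and forest
#'   fits.
#' @return A [BoostedForestModel-class].
#' @export
fitBoostedForest <- function(dataset, params = boostParams(),
                             threshold = 0.44, seed = NULL) {
  stopifnot(is(dataset, "LabeledDataset"), inherits(params, "boostParams"))
  X <- featureMatrix(dataset)
  y <- sampleLabels(dataset)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (min(table(y)) < 2L)
    stop("each class needs at least 2 samples")
  n <- nrow(X)

  withSeed(seed, {
    w <- rep(1 / n, n)
    learners <- list()
    alphas <- numeric(0)
    for (t in seq_len(params$rounds)) {
      roundSeed <- sample.int(.Machine$integer.max, 1L)
      forest <- .fitBaseForest(X, y, w, params, roundSeed)
      pred <- as.integer(.baseProb(forest, X) >= 0.5)
      err <- pred != y
      eps <- sum(w[err])
      if (eps <= 0) {
        learners[[length(learners) + 1L]] <- forest
        alphas <- c(alphas, params$learningRate * ALPHA_MAX)
        break
      }
      if (eps >= 0.5) {
        alpha <- params$learningRate * 0.5 * log((1 - eps) / eps)
        learners[[length(learners) + 1L]] <- forest
        alphas <- c(alphas, max(alpha, 0))
        break
      }
      alpha <- params$learningRate * 0.5 * log((1 - eps) / eps)
      learners[[length(learners) + 1L]] <- forest
      alphas <- c(alphas, alpha)
      w[err] <- w[err] * exp(alpha)
      w <- w / sum(w)
    }
    new("BoostedForestModel", learners = learners, alphas = alphas,
        rounds = length(learners), learningRate = params$learningRate,
        featureNames = colnames(X), threshold = threshold,
        params = params[c("nTrees", "maxDepth")])
  })
}

.checkSignature <- function(model, features) {
  if (is.null(colnames(features)) ||
      !identical(colnames(features), model@featureNames)) {
    stop("feature signature mismatch: input columns do not match the ",
         "model's training features (names and order must be identical)")
  }
}

#' Predict positive-class scores
#'
#' In the default `"probability"` mode the score is the
#' \eqn{\alpha}-weighted mean of the base forests' positive-class
#' probabilities, \eqn{\sum_t \alpha_t p_t(x) / \sum_t \alpha_t}, bounded
#' in \[0, 1\]. In `"vote"` mode each learner casts a hard \eqn{\pm 1}
#' vote and the score is 1 when \eqn{\mathrm{sign}(\sum_t \alpha_t h_t(x))}
#' is positive, 0 otherwise.
#'
#' @param model A [BoostedForestModel-class].
#' @param features Numeric matrix whose column names match the model's
#'   feature signature exactly.
#' @param type `"probability"` (default) or `"vote"`.
#' @return Numeric vector of scores in \[0, 1\], one per row.
#' @export
predictScore <- function(model, features, type = c("probability", "vote")) {
  type <- match.arg(type)
  stopifnot(is(model, "BoostedForestModel"))
  features <- as.matrix(features)
  .checkSignature(model, features)
  probs <- vapply(model@learners, function(l) .baseProb(l, features),
                  numeric(nrow(features)))
  if (nrow(features) == 1L) probs <- matrix(probs, nrow = 1L)
  a <- model@alphas
  if (type == "probability") {
    if (sum(a) <= 0) return(rowMeans(probs))
    as.vector(probs %*% a) / sum(a)
  } else {
    votes <- ifelse(probs >= 0.5, 1, -1)
    margin <- as.vector(votes %*% a)
    as.numeric(margin > 0)
  }
}

#' Turn scores into yes/no calls
#'
#' A sample is called `"yes"` when its score is greater than or equal to
#' the threshold (the boundary is inclusive).
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision threshold in (0, 1); 0.44 is the default
#'   operating point for pair prediction, 0.48 for aptamer prediction.
#' @return Character vector of `"yes"`/`"no"`.
#' @export
classifyScores <- function(scores, threshold = 0.44) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  ifelse(scores >= threshold, "yes", "no")
}

#' Save / load a fitted model archive
#'
#' The archive is a single serialized file holding the model together with
#' a format version and its feature signature; loading refuses archives
#' written by an incompatible format version.
#'
#' @param model A [BoostedForestModel-class].
#' @param path Archive path.
#' @return `saveModel`: invisibly, `path`. `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "BoostedForestModel"))
  saveRDS(list(format = "aptaboost-model-1", model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "aptaboost-model-1"))
    stop("not an aptaboost model archive (or incompatible version)")
  validObject(obj$model)
  obj$model
}
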