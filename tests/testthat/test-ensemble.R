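sepData <- function(n = 60, gap = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n), n / 2, 2),
             matrix(rnorm(n, gap), n / 2, 2))
  colnames(X) <- c("f1", "f2")
  labeledDataset(X, rep(c(0L, 1L), each = n / 2))
}

test_that("a round with weighted error one-half gets weight zero and stops", {
  # identical feature rows with balanced contradictory labels: any base
  # forest predicts one class for every row, so epsilon is exactly 1/2
  X <- matrix(1, 8, 2, dimnames = list(NULL, c("f1", "f2")))
  ds <- labeledDataset(X, rep(c(0L, 1L), each = 4))
  m <- fitBoostedForest(ds, boostParams(rounds = 10), seed = 2)
  expect_identical(m@rounds, 1L)
  expect_identical(m@alphas, 0)
})

test_that("linearly separable data is fit to training accuracy one", {
  ds <- sepData()
  m <- fitBoostedForest(ds, boostParams(rounds = 20), seed = 3)
  scores <- predictScore(m, featureMatrix(ds))
  expect_identical(as.integer(scores >= 0.5), sampleLabels(ds))
})

test_that("training is deterministic given a seed", {
  ds <- sepData(gap = 1.2, seed = 4)
  m1 <- fitBoostedForest(ds, boostParams(rounds = 5), seed = 9)
  m2 <- fitBoostedForest(ds, boostParams(rounds = 5), seed = 9)
  expect_identical(m1@alphas, m2@alphas)
  expect_identical(predictScore(m1, featureMatrix(ds)),
                   predictScore(m2, featureMatrix(ds)))
})

test_that("scores are the alpha-weighted mean of base-forest probabilities", {
  ds <- sepData(gap = 1, seed = 5)
  m <- fitBoostedForest(ds, boostParams(rounds = 3), seed = 6)
  X <- featureMatrix(ds)
  probs <- sapply(m@learners, function(l) aptaboost:::.baseProb(l, X))
  expect_equal(predictScore(m, X),
               as.vector(probs %*% m@alphas) / sum(m@alphas))
  # T = 1: the weight cancels and the score is the single forest's prob
  m1 <- fitBoostedForest(ds, boostParams(rounds = 1), seed = 7)
  expect_equal(predictScore(m1, X),
               aptaboost:::.baseProb(m1@learners[[1]], X))
  # learning rate near zero with T = 1 degenerates the same way
  m0 <- fitBoostedForest(ds, boostParams(rounds = 1,
                                         learningRate = 1e-8), seed = 7)
  expect_equal(predictScore(m0, X),
               aptaboost:::.baseProb(m0@learners[[1]], X))
})

test_that("deep in the positive region every base probability is one", {
  ds <- sepData(gap = 6, seed = 8)
  m <- fitBoostedForest(ds, boostParams(rounds = 3), seed = 8)
  far <- matrix(c(6, 6), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(predictScore(m, far), 1)
})

test_that("hard-vote aggregation agrees with the sign rule", {
  ds <- sepData(gap = 1, seed = 10)
  m <- fitBoostedForest(ds, boostParams(rounds = 5), seed = 11)
  X <- featureMatrix(ds)
  probs <- sapply(m@learners, function(l) aptaboost:::.baseProb(l, X))
  margin <- as.vector(ifelse(probs >= 0.5, 1, -1) %*% m@alphas)
  v <- predictScore(m, X, type = "vote")
  expect_equal(v, as.numeric(margin > 0))
  expect_identical(classifyScores(v, 0.5),
                   ifelse(margin > 0, "yes", "no"))
})

test_that("classification threshold boundary is inclusive and validated", {
  expect_identical(classifyScores(0.44, 0.44), "yes")
  expect_identical(classifyScores(0.439, 0.44), "no")
  expect_identical(classifyScores(c(0.5, 0.47), 0.48), c("yes", "no"))
  expect_error(classifyScores(0.5, 0), "threshold")
  expect_error(classifyScores(0.5, 1), "threshold")
})

test_that("raising the threshold never increases yes calls", {
  set.seed(12)
  scores <- runif(200)
  yes <- vapply(seq(0.05, 0.95, by = 0.05),
                function(t) sum(classifyScores(scores, t) == "yes"),
                numeric(1))
  expect_true(all(diff(yes) <= 0))
})

test_that("prediction refuses a mismatched feature signature", {
  ds <- sepData()
  m <- fitBoostedForest(ds, boostParams(rounds = 2), seed = 13)
  X <- featureMatrix(ds)
  bad <- X; colnames(bad) <- c("f2", "f1")
  expect_error(predictScore(m, bad), "signature")
  expect_error(predictScore(m, unname(X)), "signature")
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(fitBoostedForest(labeledDataset(X, rep(1L, 10))),
               "both classes")
  expect_error(labeledDataset(matrix(c(1, Inf), 1, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              1L),
               "finite")
})

test_that("model archives round-trip and refuse foreign files", {
  ds <- sepData()
  m <- fitBoostedForest(ds, boostParams(rounds = 2), seed = 14)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(m2@alphas, m@alphas)
  expect_identical(predictScore(m2, featureMatrix(ds)),
                   predictScore(m, featureMatrix(ds)))
  saveRDS(list(whatever = 1), f)
  expect_error(loadModel(f), "archive")
})
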