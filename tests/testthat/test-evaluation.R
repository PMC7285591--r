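test_that("confusion metrics evaluate the defining formulas exactly", {
  # TP=3, FP=1, TN=4, FN=2
  labels <- c(rep(1, 5), rep(0, 5))
  preds <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- confusionMetrics(labels, preds)
  expect_equal(m$Sn, 0.6)
  expect_equal(m$Sp, 0.8)
  expect_equal(m$Acc, 0.7)
  expect_equal(m$Precision, 0.75)
  expect_equal(m$F1, 2 / 3, tolerance = 1e-12)
  expect_equal(m$MCC, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6),
               tolerance = 1e-12)
  expect_equal(round(m$MCC, 4), 0.4082)

  perfect <- confusionMetrics(labels, labels)
  for (k in c("Sn", "Sp", "Acc", "MCC", "F1", "Precision")) {
    expect_equal(perfect[[k]], 1)
  }
})

test_that("degenerate all-positive predictions use the zero conventions", {
  labels <- rep(c(1, 0), each = 4)
  m <- confusionMetrics(labels, rep(1, 8))
  expect_equal(m$Sn, 1)
  expect_equal(m$Sp, 0)
  expect_equal(m$MCC, 0)
  # all-negative: precision and F1 fall back to 0
  m2 <- confusionMetrics(labels, rep(0, 8))
  expect_equal(m2$Precision, 0)
  expect_equal(m2$F1, 0)
  expect_error(confusionMetrics(rep(1, 4), rep(1, 4)), "both classes")
  expect_error(confusionMetrics(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("metrics are invariant under joint permutation and class swap", {
  set.seed(40)
  labels <- rbinom(30, 1, 0.5); labels[1:2] <- c(0, 1)
  preds <- rbinom(30, 1, 0.5)
  perm <- sample(30)
  expect_equal(confusionMetrics(labels, preds),
               confusionMetrics(labels[perm], preds[perm]))
  # MCC is symmetric under swapping the positive convention everywhere
  expect_equal(confusionMetrics(labels, preds)$MCC,
               confusionMetrics(1 - labels, 1 - preds)$MCC)
})

test_that("AUC equals the concordant-pair count and behaves at extremes", {
  labels <- rep(c(1, 0), each = 5)
  expect_equal(rocAuc(labels, c(2, 3, 4, 5, 6, -1, 0, 1, 1.5, 1.9)), 1)
  expect_equal(rocAuc(labels, rep(0.7, 10)), 0.5)
  set.seed(41)
  for (i in 1:10) {
    lab <- rbinom(20, 1, 0.5); lab[1:2] <- c(0, 1)
    sc <- sample(seq(0, 1, by = 0.1), 20, replace = TRUE)  # many ties
    expect_equal(rocAuc(lab, sc), oracleAUC(lab, sc), tolerance = 1e-12)
    expect_equal(rocAuc(lab, sc) + rocAuc(lab, -sc), 1, tolerance = 1e-12)
  }
})

test_that("ROC points sweep all thresholds from (0,0) to (1,1)", {
  set.seed(42)
  labels <- rep(c(1, 0), each = 10)
  scores <- runif(20)
  roc <- rocCurve(labels, scores)
  expect_equal(roc$points$Sn[1], 0)
  expect_equal(roc$points$FPR[1], 0)
  expect_equal(roc$points$Sn[nrow(roc$points)], 1)
  expect_equal(roc$points$FPR[nrow(roc$points)], 1)
  expect_true(all(diff(roc$points$Sn) >= 0))
  expect_true(all(diff(roc$points$FPR) >= 0))
})

test_that("DeLong test is consistent with its AUCs and with pROC", {
  set.seed(43)
  labels <- rep(c(1, 0), each = 40)
  a <- rnorm(80, labels)
  b <- rnorm(80, 0.3 * labels)
  res <- delongTest(labels, a, b)
  expect_equal(res$aucA, rocAuc(labels, a), tolerance = 1e-12)
  expect_equal(res$aucB, rocAuc(labels, b), tolerance = 1e-12)
  # identical scores: p = 1 by convention
  expect_equal(delongTest(labels, a, a)$p, 1)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong")
  expect_equal(res$p, unname(ref$p.value), tolerance = 1e-8)
})

test_that("stratified splits partition both classes at the requested rate", {
  labels <- rep(c(0, 1), c(80, 20))
  sp <- stratifiedSplit(labels, 0.25, seed = 44)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sum(labels[sp$test] == 1), 5L)
  expect_identical(sum(labels[sp$test] == 0), 20L)
})
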