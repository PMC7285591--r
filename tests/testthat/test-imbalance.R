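mkDataset <- function(X, y) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  labeledDataset(X, y)
}

test_that("SMOTE interpolates on segments between minority neighbors", {
  # two identical minority points: every synthetic point equals them
  X <- rbind(matrix(5, 2, 3), matrix(rnorm(30), 10, 3))
  ds <- mkDataset(X, rep(c(1L, 0L), c(2, 10)))
  out <- smote(ds, kNeighbors = 1, seed = 1)
  synth <- featureMatrix(out)[sampleProvenance(out) == "synthetic", ,
                              drop = FALSE]
  expect_identical(nrow(synth), 8L)
  expect_true(all(synth == 5))

  # two distinct minority points: synthetic points lie on the segment
  a <- c(0, 0, 0); b <- c(1, 2, 3)
  X2 <- rbind(a, b, matrix(10 + rnorm(30), 10, 3))
  ds2 <- mkDataset(X2, rep(c(1L, 0L), c(2, 10)))
  out2 <- smote(ds2, kNeighbors = 1, seed = 2)
  synth2 <- featureMatrix(out2)[sampleProvenance(out2) == "synthetic", ,
                                drop = FALSE]
  u <- synth2[, 1] / (b - a)[1]
  expect_true(all(u >= 0 & u <= 1))
  expect_equal(synth2, outer(u, b - a) +
                 matrix(a, nrow(synth2), 3, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("SMOTE produces the requested counts and respects bounds", {
  set.seed(3)
  X <- matrix(rnorm(2243 * 3), ncol = 3)
  y <- rep(c(1L, 0L), c(561, 1682))
  ds <- mkDataset(X, y)
  out <- smote(ds, seed = 4)
  expect_identical(sum(sampleLabels(out) == 1L), 1682L)
  expect_identical(sum(sampleProvenance(out) == "synthetic"), 1121L)

  # synthetic rows stay inside the minority bounding box
  Xmin <- featureMatrix(ds)[y == 1L, ]
  synth <- featureMatrix(out)[sampleProvenance(out) == "synthetic", ]
  for (j in 1:3) {
    expect_gte(min(synth[, j]), min(Xmin[, j]))
    expect_lte(max(synth[, j]), max(Xmin[, j]))
  }
  # majority rows pass through bitwise
  expect_identical(featureMatrix(out)[seq_len(nrow(X)), ],
                   featureMatrix(ds))
})

test_that("SMOTE is seed-reproducible and seed-sensitive", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  ds <- mkDataset(X, rep(c(1L, 0L), c(6, 14)))
  a <- smote(ds, seed = 10)
  b <- smote(ds, seed = 10)
  c <- smote(ds, seed = 11)
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_false(identical(featureMatrix(a), featureMatrix(c)))
})

test_that("every synthetic point is a convex combination of two minority points", {
  set.seed(6)
  X <- matrix(rnorm(10 * 4), 10, 4)
  ds <- mkDataset(X, rep(c(1L, 0L), c(4, 6)))
  out <- smote(ds, kNeighbors = 3, targetCount = 20, seed = 7)
  Xmin <- featureMatrix(ds)[1:4, ]
  synth <- featureMatrix(out)[sampleProvenance(out) == "synthetic", ]
  for (r in seq_len(nrow(synth))) {
    found <- FALSE
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      den <- Xmin[j, ] - Xmin[i, ]
      u <- (synth[r, ] - Xmin[i, ]) / ifelse(den == 0, 1, den)
      uu <- u[den != 0]
      onSeg <- all(abs(synth[r, den == 0] - Xmin[i, den == 0]) < 1e-10)
      if (length(uu) == 0) uu <- 0
      if (onSeg && diff(range(uu)) < 1e-8 &&
          uu[1] >= -1e-10 && uu[1] <= 1 + 1e-10) found <- TRUE
    }
    expect_true(found)
  }
})

test_that("SMOTE rejects degenerate requests", {
  X <- matrix(rnorm(30), 10, 3)
  ds <- mkDataset(X, rep(c(1L, 0L), c(1, 9)))
  expect_error(smote(ds), "at least 2")
  ds2 <- mkDataset(X, rep(c(1L, 0L), c(4, 6)))
  expect_error(smote(ds2, targetCount = 2), "below")
})
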