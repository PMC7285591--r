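test_that("AAC matches direct counting and is permutation-invariant", {
  expect_equal(unname(encodeAAC("AAAA")[1, "AAC.A"]), 1)
  v <- encodeAAC("ACDC")[1, ]
  expect_equal(unname(v[c("AAC.A", "AAC.C", "AAC.D")]), c(0.25, 0.5, 0.25))
  expect_equal(sum(v), 1)
  set.seed(4)
  s <- randomProteinSeq(60)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(encodeAAC(s)[1, ], encodeAAC(perm)[1, ])
})

test_that("GAAC uses the five-group partition and sums to one", {
  v <- encodeGAAC("GAVLFD")[1, ]
  expect_equal(unname(v), c(4 / 6, 1 / 6, 0, 1 / 6, 0))
  expect_equal(unname(encodeGAAC("KKKK")[1, "GAAC.positive_charge"]), 1)
  set.seed(5)
  for (i in 1:10) expect_equal(sum(encodeGAAC(randomProteinSeq(30))), 1)
})

test_that("PseAAC matches a term-by-term oracle and normalizes to one", {
  v <- encodePseAAC("AAAAA", lambda = 2, w = 0.05)[1, ]
  expect_equal(unname(v["PseAAC.A"]), 1)
  expect_equal(unname(v[c("PseAAC.lambda1", "PseAAC.lambda2")]), c(0, 0))

  set.seed(6)
  for (i in 1:20) {
    s <- randomProteinSeq(sample(10:50, 1))
    lam <- sample(c(1, 3, 5), 1)
    got <- encodePseAAC(s, lambda = lam, w = 0.05)[1, ]
    expect_equal(unname(got), oraclePseAAC(s, lam, 0.05), tolerance = 1e-12)
    expect_equal(sum(got), 1)
  }
  expect_error(encodePseAAC("ACDEF", lambda = 10), "shorter")
})

test_that("CTDC computes per-attribute class frequencies", {
  v <- encodeCTDC("RRGG")[1, ]
  expect_equal(unname(v[paste0("CTDC.hydrophobicity.G", 1:3)]),
               c(0.5, 0.5, 0))
  # each attribute triple is a partition of the sequence
  set.seed(7)
  v2 <- encodeCTDC(randomProteinSeq(40))[1, ]
  for (p in names(ctdGroups())) {
    expect_equal(sum(v2[paste0("CTDC.", p, ".G", 1:3)]), 1)
  }
  # single residue: every attribute triple is a one-hot
  w <- encodeCTDC("W")[1, ]
  expect_true(all(tapply(w, rep(1:7, each = 3), max) == 1))
})

test_that("SOCN matches the embedded matrices and a double-loop oracle", {
  v <- encodeSOCN("AC", lambda = 1)[1, ]
  expect_equal(unname(v["SOCN.physchem.d1"]),
               unname(physchemMatrix()["A", "C"]^2))
  expect_equal(unname(v["SOCN.grantham.d1"]),
               unname(granthamMatrix()["A", "C"]^2))
  expect_true(all(encodeSOCN(strrep("A", 40))[1, ] == 0))
  expect_error(encodeSOCN(randomProteinSeq(10), lambda = 30),
               "minimum length")
  set.seed(8)
  for (i in 1:15) {
    s <- randomProteinSeq(sample(12:50, 1))
    got <- encodeSOCN(s, lambda = 8)[1, ]
    expect_equal(unname(got), oracleSOCN(s, 8), tolerance = 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("Grantham matrix reproduces published distances", {
  G <- granthamMatrix()
  expect_equal(unname(G["S", "R"]), 110, tolerance = 0.02)
  expect_equal(unname(G["L", "I"]), 5, tolerance = 0.05)
  expect_equal(unname(G["W", "C"]), 215, tolerance = 0.02)
  expect_true(all(diag(G) == 0))
  expect_equal(G, t(G))
})

test_that("order-sensitive encoders change under adjacent transposition", {
  set.seed(9)
  s <- "ACDEFGHIKLMNPQRSTVWYACDEFGHIKL"
  swapped <- paste0(substr(s, 1, 4), substr(s, 6, 6), substr(s, 5, 5),
                    substr(s, 7, nchar(s)))
  expect_false(isTRUE(all.equal(encodePseAAC(s, 5)[1, ],
                                encodePseAAC(swapped, 5)[1, ])))
  expect_false(isTRUE(all.equal(encodeSOCN(s, 5)[1, ],
                                encodeSOCN(swapped, 5)[1, ])))
  # order-free encoders do not
  expect_equal(encodeAAC(s)[1, ], encodeAAC(swapped)[1, ])
  expect_equal(encodeGAAC(s)[1, ], encodeGAAC(swapped)[1, ])
  expect_equal(encodeCTDC(s)[1, ], encodeCTDC(swapped)[1, ])
})

test_that("encodeProtein concatenates configured encoders with stable dims", {
  s <- setNames(randomProteinSeq(100), "p")
  expect_identical(ncol(encodeProtein(s, proteinEncoderConfig(
    encoders = c("AAC", "GAAC")))), 25L)
  expect_identical(ncol(encodeProtein(s)), 156L)
  expect_error(proteinEncoderConfig(encoders = character(0)), "empty")
  expect_error(proteinEncoderConfig(encoders = "XYZ"), "unknown")
  # sequences with non-canonical letters are rejected, not skipped
  expect_error(encodeProtein(c(p = "ACDEFX")), "outside")
})
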