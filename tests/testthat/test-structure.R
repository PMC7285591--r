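test_that("dot-bracket parsing yields the hand-traced statistics", {
  r <- parseDotBracket("GGGAAACCC", "(((...)))", energy = -3)
  s <- structureStats(r)
  expect_identical(s$pairCount, 3L)
  expect_identical(s$hairpinCount, 1L)
  expect_equal(s$unpairedFraction, 3 / 9)
  expect_identical(s$stemCount, 1L)
  expect_identical(s$longestStem, 3L)
  expect_equal(s$energyDensity, -3 / 9)

  r2 <- parseDotBracket("AAAAAAAAA", ".........", energy = 0)
  expect_identical(structureStats(r2)$pairCount, 0L)
  expect_equal(structureStats(r2)$unpairedFraction, 1)

  expect_error(parseDotBracket("GGG", "((("), "unbalanced")
  expect_error(parseDotBracket("GGG", ")))"), "unbalanced")
  expect_error(parseDotBracket("GGGG", "((("), "length")
  expect_error(parseDotBracket("GGG", "(x)"), "only")
})

test_that("bulges and internal loops are classified by one-sided gaps", {
  rb <- parseDotBracket("GGAGGAAACCCC", "((.((...))))")
  sb <- structureStats(rb)
  expect_identical(sb$bulgeCount, 1L)
  expect_identical(sb$internalLoopCount, 0L)
  expect_identical(sb$stemCount, 2L)
  expect_identical(sb$longestStem, 2L)

  ri <- parseDotBracket("GGAGGAAACCACC", "((.((...)).))")
  si <- structureStats(ri)
  expect_identical(si$internalLoopCount, 1L)
  expect_identical(si$bulgeCount, 0L)
})

test_that("dot-bracket survives a parse/serialize round trip", {
  set.seed(20)
  for (i in 1:20) {
    s <- randomDnaSeq(sample(10:40, 1))
    rec <- nussinovFold(s)
    again <- parseDotBracket(s, dotBracket(rec), energy = rec@energy)
    expect_identical(dotBracket(again), dotBracket(rec))
    expect_identical(structureStats(again), structureStats(rec))
  }
})

test_that("the folder maximizes pairs with the minimum hairpin size", {
  r <- nussinovFold("GGGAAACCC")
  expect_identical(structureStats(r)$pairCount, 3L)
  expect_identical(dotBracket(r), "(((...)))")
  expect_identical(structureStats(nussinovFold("AAAAAA"))$pairCount, 0L)
  # no admissible i, j with j - i > 3 exists
  expect_identical(structureStats(nussinovFold("GCGC"))$pairCount, 0L)
  # DNA folds with T treated as U (including the G-T wobble)
  expect_identical(structureStats(nussinovFold("GGGAAATCC"))$pairCount, 3L)
  expect_error(nussinovFold("ACGX"), "invalid")
})

test_that("folded pair counts equal exhaustive enumeration up to length 12", {
  set.seed(21)
  for (i in 1:60) {
    s <- randomDnaSeq(sample(4:12, 1))
    expect_identical(structureStats(nussinovFold(s))$pairCount,
                     oracleMaxPairs(s))
  }
})

test_that("aptamer-likeness evaluates the documented predicate", {
  unpaired <- parseDotBracket("AAAAAAAAAA", "..........", energy = 0)
  expect_false(aptamerLikeness(unpaired))
  stable <- nussinovFold("GGGGGGAAACCCCCC")
  expect_true(aptamerLikeness(stable))
  # extreme thresholds push every record to one side
  loose <- screeningThresholds(maxEnergyDensity = 1e6,
                               maxUnpairedFraction = 1,
                               minHairpins = 0, minLongestStem = 0)
  strict <- screeningThresholds(maxEnergyDensity = -1e6)
  for (rec in list(unpaired, stable)) {
    expect_true(aptamerLikeness(rec, loose))
    expect_false(aptamerLikeness(rec, strict))
  }
})

test_that("RNAfold-style structure text parses names, brackets and energy", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">apt1", "GGGAAACCC", "(((...))) (-4.20)",
               "ACGUACGUA", "......... ( 0.00)"), f)
  recs <- readViennaStructures(f)
  expect_length(recs, 2)
  expect_identical(recs[[1]]@name, "apt1")
  expect_equal(recs[[1]]@energy, -4.2)
  expect_identical(structureStats(recs[[1]])$pairCount, 3L)
  expect_identical(recs[[2]]@name, "structure_2")
  writeLines(c(">apt1", "GGGAAACCC"), f)
  expect_error(readViennaStructures(f), "truncated")
})

test_that("generated negatives all fail the screen and match lengths", {
  pos <- makeAptamerBenchmark(300, seed = 30)
  neg <- suppressMessages(generateNegatives(pos, 300, "DNA", seed = 31))
  expect_length(neg, 300)
  # by construction, and asserted anyway: every negative fails the screen
  likeness <- vapply(as.character(neg), function(s)
    aptamerLikeness(nussinovFold(s)), logical(1))
  expect_false(any(likeness))
  # reproducibility
  neg2 <- suppressMessages(generateNegatives(pos, 300, "DNA", seed = 31))
  expect_identical(as.character(neg), as.character(neg2))
  # length distributions agree at histogram resolution
  br <- seq(15, 105, by = 10)
  pl <- table(cut(nchar(pos), br)) / length(pos)
  nl <- table(cut(nchar(as.character(neg)), br)) / length(neg)
  expect_lt(sum(abs(pl - nl)) / 2, 0.12)
})

test_that("screens that reject nothing return the first candidates drawn", {
  pos <- makeAptamerBenchmark(40, seed = 32)
  never <- screeningThresholds(maxEnergyDensity = -1e6)  # nothing passes
  neg <- suppressMessages(
    generateNegatives(pos, 40, "DNA", thresholds = never, seed = 33))
  md <- S4Vectors::metadata(neg)
  expect_identical(md$attempts, 40L)
  expect_identical(md$rejectedAptamerLike, 0L)
})

test_that("length statistics report mode, window fraction and histogram", {
  s <- c(a = strrep("A", 40), b = strrep("C", 40), c = strrep("G", 30))
  ls <- lengthStats(s)
  expect_identical(ls$mode, 40L)
  expect_equal(ls$fractionWithin, 1)
  expect_error(lengthStats(character(0)), "empty")
  # smallest length wins a tie
  ls2 <- lengthStats(c(x = "AA", y = "CCC"))
  expect_identical(ls2$mode, 2L)
})
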