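## Synthetic data generator. Emulates the shapes of the study data: random
## valid protein/nucleotide sequences, an aptamer-like length distribution
## (modal length 40 nt, secondary modes 30/50/80 nt, ~80% of mass in
## 30-80 nt), planted-signal pair datasets for end-to-end tests, and
## supplementary-shaped benchmark tables with known partition counts plus
## planted problematic rows for exercising the dataset plumbing.

## Fixed tilt directions used to plant a compositional signal: positive
## samples are drawn from letter distributions proportional to
## exp(shift * tilt).
.aaTilt <- function() {
  setNames(rep(c(1, -1), 10), AA_LETTERS)
}
.baseTilt <- function() c(A = 1, C = -1, G = 1, T = -1)

.tiltedProbs <- function(tilt, shift) {
  p <- exp(shift * tilt)
  p / sum(p)
}

#' Sample aptamer-like sequence lengths
#'
#' Draws lengths from a fixed discrete distribution shaped like the
#' empirical aptamer length distribution: 80% of the mass lies in
#' 30-80 nt with the modal length at 40 nt and secondary peaks at 30, 50
#' and 80 nt; the remaining 20% is spread uniformly over the SELEX-typical
#' flanks 20-29 and 81-100 nt.
#'
#' @param n Number of lengths.
#' @param seed Integer seed.
#' @return Integer vector of lengths.
#' @export
sampleAptamerLengths <- function(n, seed = NULL) {
  lens <- c(30:80, 20:29, 81:100)
  w <- c(rep(1, 51), rep(0, 30))
  names(w) <- lens
  w["40"] <- 8; w["30"] <- 4; w["50"] <- 4; w["80"] <- 4
  inRange <- lens >= 30 & lens <= 80
  w[inRange] <- 0.8 * w[inRange] / sum(w[inRange])
  w[!inRange] <- 0.2 / sum(!inRange)
  withSeed(seed, sample(lens, n, replace = TRUE, prob = w))
}

#' Random valid protein sequences
#'
#' @param n Number of sequences.
#' @param lengthRange Inclusive length bounds (default 60-200, long
#'   enough for the default encoder configuration).
#' @param probs Per-letter probabilities over the 20 amino acids
#'   (default uniform).
#' @param seed Integer seed.
#' @param prefix Name prefix.
#' @return Named character vector of protein sequences.
#' @export
randomProteins <- function(n, lengthRange = c(60, 200), probs = NULL,
                           seed = NULL, prefix = "prot") {
  if (is.null(probs)) probs <- rep(1 / 20, 20)
  withSeed(seed, {
    lens <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_LETTERS, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    setNames(seqs, sprintf("%s_%04d", prefix, seq_len(n)))
  })
}

#' Random valid nucleotide sequences
#'
#' @param n Number of sequences.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param lengths Explicit lengths, or `NULL` to draw from
#'   [sampleAptamerLengths()].
#' @param probs Base probabilities in A, C, G, T/U order (default
#'   uniform).
#' @param seed Integer seed.
#' @param prefix Name prefix.
#' @return Named character vector of nucleotide sequences.
#' @export
randomNucleotides <- function(n, molecule = c("DNA", "RNA"),
                              lengths = NULL, probs = NULL, seed = NULL,
                              prefix = "apt") {
  molecule <- match.arg(molecule)
  if (is.null(probs)) probs <- rep(1 / 4, 4)
  letters4 <- if (molecule == "DNA") DNA_LETTERS else RNA_LETTERS
  withSeed(seed, {
    if (is.null(lengths)) lengths <- sampleAptamerLengths(n)
    seqs <- vapply(lengths, function(L)
      paste(sample(letters4, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    setNames(seqs, sprintf("%s_%04d", prefix, seq_len(n)))
  })
}

#' Planted-signal protein-aptamer pair dataset
#'
#' Builds a binary pair dataset in which the two classes differ by a
#' compositional tilt: sequences of positive pairs are drawn from letter
#' distributions proportional to `exp(shift * tilt)` for a fixed
#' alternating tilt vector, negatives from the untilted distributions.
#' `shift = 0` therefore yields a pure null (no separation); large `shift`
#' yields near-perfect separation through any composition-sensitive
#' encoder.
#'
#' @param nPos,nNeg Pair counts per class.
#' @param shift Tilt strength (default 0.5, a clear planted signal).
#' @param molecule Aptamer molecule kind.
#' @param seed Integer seed.
#' @return A pair data frame in the layout of [loadPairDataset()].
#' @export
plantedPairDataset <- function(nPos, nNeg, shift = 0.5,
                               molecule = c("DNA", "RNA"), seed = NULL) {
  molecule <- match.arg(molecule)
  withSeed(seed, {
    aaPos <- .tiltedProbs(.aaTilt(), shift)
    ntPos <- .tiltedProbs(.baseTilt(), shift)
    protPos <- randomProteins(nPos, probs = aaPos, prefix = "protP")
    protNeg <- randomProteins(nNeg, prefix = "protN")
    aptPos <- randomNucleotides(nPos, molecule, probs = ntPos,
                                prefix = "aptP")
    aptNeg <- randomNucleotides(nNeg, molecule, prefix = "aptN")
    data.frame(
      protein_id = c(names(protPos), names(protNeg)),
      protein_seq = c(unname(protPos), unname(protNeg)),
      aptamer_id = c(names(aptPos), names(aptNeg)),
      aptamer_seq = c(unname(aptPos), unname(aptNeg)),
      label = rep(c(1L, 0L), c(nPos, nNeg)),
      stringsAsFactors = FALSE
    )
  })
}

## Rows the problematic-sequence filter must discard, with all three
## defect kinds represented.
.problematicRows <- function(n, molecule, seed = NULL) {
  withSeed(seed, {
    base <- randomNucleotides(n, molecule, lengths = rep(40L, n),
                              prefix = "bad")
    prot <- randomProteins(n, prefix = "badprot")
    kind <- rep(c("N", "B", "UT"), length.out = n)
    seqs <- vapply(seq_len(n), function(i) {
      s <- base[[i]]
      if (kind[i] == "N") sub("A", "N", paste0(s, "A"))
      else if (kind[i] == "B") paste0(s, "B")
      else if (molecule == "DNA") paste0(s, "TU") else paste0(s, "UT")
    }, character(1))
    data.frame(protein_id = names(prot), protein_seq = unname(prot),
               aptamer_id = names(base), aptamer_seq = seqs,
               label = rep(c(0L, 1L), length.out = n),
               stringsAsFactors = FALSE)
  })
}

#' Synthetic interaction benchmark with known partition counts
#'
#' Builds a synthetic protein-aptamer interaction benchmark shaped like
#' the study's interaction tables: a train partition that contains exactly
#' `trainPos`/`trainNeg` clean pairs (default 561/1682) and a test
#' partition with `testPos`/`testNeg` (default 143/421), both with a
#' planted compositional signal, plus `nProblematic` rows per partition
#' whose aptamer sequences carry the three defect kinds (`N`, `B`, mixed
#' U/T) and must be removed by the problematic-sequence filter before the
#' counts come out right. Row order is shuffled.
#'
#' @param trainPos,trainNeg,testPos,testNeg Clean pair counts.
#' @param nProblematic Planted defective rows per partition (default 24).
#' @param shift Planted signal strength (see [plantedPairDataset()]).
#' @param molecule Aptamer molecule kind.
#' @param seed Integer seed.
#' @return A list with data frames `train` and `test` (raw, unfiltered).
#' @export
makeInteractionBenchmark <- function(trainPos = 561, trainNeg = 1682,
                                     testPos = 143, testNeg = 421,
                                     nProblematic = 24, shift = 0.5,
                                     molecule = c("DNA", "RNA"),
                                     seed = NULL) {
  molecule <- match.arg(molecule)
  withSeed(seed, {
    build <- function(nPos, nNeg) {
      clean <- plantedPairDataset(nPos, nNeg, shift = shift,
                                  molecule = molecule)
      raw <- rbind(clean, .problematicRows(nProblematic, molecule))
      raw[sample(nrow(raw)), , drop = FALSE]
    }
    list(train = build(trainPos, trainNeg),
         test = build(testPos, testNeg))
  })
}

#' Synthetic positive aptamer set shaped like the study's
#'
#' Generates `n` (default 704) sequences whose length distribution follows
#' [sampleAptamerLengths()]. Each positive is constructed as a stem-loop:
#' a random sequence with an embedded inverted repeat (stem fraction
#' 25-40% of the length, loop of 3-8 nt, random flanking tails), screened
#' to pass [aptamerLikeness()] — emulating that real aptamers fold into
#' robust stem-loop structures, and making the positive class by
#' construction the structural complement of the negatives produced by
#' [generateNegatives()]. The target length is fixed before construction,
#' so the length distribution is preserved exactly. One molecule kind per
#' call.
#'
#' @param n Number of aptamers (default 704).
#' @param molecule Molecule kind.
#' @param screened Keep only candidates passing [aptamerLikeness()]?
#' @param thresholds Screening thresholds used when `screened = TRUE`.
#' @param seed Integer seed.
#' @param maxAttemptsPerSeq Per-sequence rejection-sampling budget.
#' @return Named character vector of sequences.
#' @export
makeAptamerBenchmark <- function(n = 704, molecule = c("DNA", "RNA"),
                                 screened = TRUE,
                                 thresholds = screeningThresholds(),
                                 seed = NULL, maxAttemptsPerSeq = 1000) {
  molecule <- match.arg(molecule)
  withSeed(seed, {
    letters4 <- if (molecule == "DNA") DNA_LETTERS else RNA_LETTERS
    compFrom <- paste(letters4, collapse = "")
    compTo <- paste(rev(letters4), collapse = "")
    lens <- sampleAptamerLengths(n)
    mkStemLoop <- function(L) {
      loop <- sample(3:8, 1L)
      s <- max(4L, round(L * runif(1, 0.25, 0.40)))
      while (2L * s + loop > L) s <- s - 1L
      rest <- L - 2L * s - loop
      t1 <- sample.int(rest + 1L, 1L) - 1L
      stem <- sample(letters4, s, replace = TRUE)
      paste(c(sample(letters4, t1, replace = TRUE), stem,
              sample(letters4, loop, replace = TRUE),
              rev(chartr(compFrom, compTo, stem)),
              sample(letters4, rest - t1, replace = TRUE)),
            collapse = "")
    }
    out <- vapply(lens, function(L) {
      for (i in seq_len(maxAttemptsPerSeq)) {
        cand <- mkStemLoop(L)
        if (!screened ||
            aptamerLikeness(nussinovFold(cand), thresholds)) {
          return(cand)
        }
      }
      stop("could not construct an aptamer-like sequence of length ", L)
    }, character(1))
    setNames(out, sprintf("aptamer_%04d", seq_len(n)))
  })
}

#' Write a full fixture bundle to disk
#'
#' Emits a protein FASTA, an aptamer FASTA and a planted-signal pair TSV,
#' all of which parse through the package's readers with zero discards.
#'
#' @param dir Output directory (created if needed).
#' @param nPairs Pairs per class in the pair table.
#' @param shift Planted signal strength.
#' @param molecule Aptamer molecule kind.
#' @param seed Integer seed.
#' @return Named list of file paths (`proteins`, `aptamers`, `pairs`).
#' @export
makeFixtures <- function(dir = tempfile("fixtures"), nPairs = 50,
                         shift = 0.5, molecule = c("DNA", "RNA"),
                         seed = NULL) {
  molecule <- match.arg(molecule)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(seed, {
    pairs <- plantedPairDataset(nPairs, nPairs, shift = shift,
                                molecule = molecule)
    prot <- setNames(pairs$protein_seq, pairs$protein_id)
    apt <- setNames(pairs$aptamer_seq, pairs$aptamer_id)
    paths <- list(
      proteins = file.path(dir, "proteins.fasta"),
      aptamers = file.path(dir, "aptamers.fasta"),
      pairs = file.path(dir, "pairs.tsv")
    )
    writeFasta(prot, paths$proteins)
    writeFasta(apt, paths$aptamers)
    write.table(pairs, paths$pairs, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths
  })
}
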