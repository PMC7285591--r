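## Secondary-structure screening used to build the negative aptamer set:
## dot-bracket parsing with loop/stem statistics, a built-in
## maximum-base-pairing folder (external RNAfold-style output can be
## supplied instead, matching its two-column text layout), an
## aptamer-likeness predicate, and the length-matched negative-sequence
## generator.

#' Parse a dot-bracket structure into a StructureRecord
#'
#' Stack-based parse of a nested dot-bracket string. Loops enclosed by a
#' base pair are classified by their immediate enclosed helices: none =
#' hairpin; one with a one-sided unpaired gap = bulge; one with gaps on
#' both sides = internal loop. Stems are maximal runs of stacked pairs
#' `(i, j), (i+1, j-1), ...`. Crossing (pseudoknotted) brackets are
#' rejected: the screen operates on nested structures only.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param dbString Dot-bracket string of the same length over
#'   `(`, `)`, `.`.
#' @param energy Folding energy in kcal/mol (or a pseudo-energy); stored
#'   and used for the energy-density statistic.
#' @param name Optional record name.
#' @return A [StructureRecord-class].
#' @export
parseDotBracket <- function(seq, dbString, energy = NA_real_,
                            name = "seq") {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (nchar(dbString) != n)
    stop("dot-bracket length must equal sequence length")
  ch <- strsplit(dbString, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket may contain only '(', ')' and '.'")
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")

  opens <- which(ch == "(")
  pairCount <- length(opens)
  unpaired <- sum(ch == ".")

  ## stems: maximal runs of stacked pairs
  stemCount <- 0L
  longestStem <- 0L
  if (pairCount > 0) {
    run <- 0L
    prev <- NULL
    for (i in opens) {
      j <- partner[i]
      if (!is.null(prev) && i == prev[1] + 1L && j == prev[2] - 1L) {
        run <- run + 1L
      } else {
        if (run > 0L) {
          stemCount <- stemCount + 1L
          longestStem <- max(longestStem, run)
        }
        run <- 1L
      }
      prev <- c(i, j)
    }
    stemCount <- stemCount + 1L
    longestStem <- max(longestStem, run)
  }

  ## loop classification per enclosing pair
  hairpin <- 0L; bulge <- 0L; internal <- 0L
  for (i in opens) {
    j <- partner[i]
    ## immediate children: pairs directly enclosed, skipping their insides
    k <- i + 1L
    children <- list()
    while (k < j) {
      if (ch[k] == "(") {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    if (length(children) == 0L) {
      hairpin <- hairpin + 1L
    } else if (length(children) == 1L) {
      a <- children[[1]][1] - i - 1L   # unpaired gap on the 5' side
      b <- j - children[[1]][2] - 1L   # unpaired gap on the 3' side
      if (a > 0L && b > 0L) internal <- internal + 1L
      else if (a > 0L || b > 0L) bulge <- bulge + 1L
      ## a == b == 0: stacked pair, part of a stem
    }
    ## >= 2 children: multiloop; not tallied by the screen
  }

  new("StructureRecord", name = name, sequence = seq,
      dotbracket = dbString, energy = as.numeric(energy),
      stats = list(pairCount = pairCount, hairpinCount = hairpin,
                   bulgeCount = bulge, internalLoopCount = internal,
                   stemCount = stemCount, longestStem = longestStem,
                   unpairedFraction = unpaired / n,
                   energyDensity = as.numeric(energy) / n))
}

#' Fold a sequence by base-pair maximization
#'
#' Nussinov-style dynamic programming maximizing the number of base pairs
#' subject to a minimum hairpin size. Allowed pairs: A-U (T is treated as
#' U, so DNA folds under the same rules), G-C and the G-U wobble. The
#' pseudo-energy is `-pairCount` — a structural score, not a thermodynamic
#' minimum free energy; an external thermodynamic engine's output can be
#' supplied via [readViennaStructures()] instead.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param minLoop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param name Optional record name.
#' @return A [StructureRecord-class] with `energy = -pairCount`.
#' @export
nussinovFold <- function(seq, minLoop = 3, name = "seq") {
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("empty sequence")
  res <- .nussinovCpp(seq, as.integer(minLoop))
  parseDotBracket(seq, res$dotbracket, energy = -res$pairs, name = name)
}

#' Read RNAfold-style structure output
#'
#' Parses the standard text layout produced by thermodynamic folding
#' engines: an optional `>name` line, the sequence line, then the
#' dot-bracket line ending in the energy in parentheses, e.g.
#' `"((((...)))) ( -4.20)"`.
#'
#' @param path Path to the text file.
#' @return A list of [StructureRecord-class] objects.
#' @export
readViennaStructures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  counter <- 0L
  while (i <= length(lines)) {
    counter <- counter + 1L
    name <- sprintf("structure_%d", counter)
    if (startsWith(lines[i], ">")) {
      name <- sub("\\s.*$", "", sub("^>", "", lines[i]))
      i <- i + 1L
    }
    if (i + 1L > length(lines)) stop("truncated structure entry: ", name)
    seq <- toupper(trimws(lines[i]))
    m <- regmatches(lines[i + 1L],
                    regexec("^([().]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                            lines[i + 1L]))[[1]]
    if (length(m) != 3L)
      stop("cannot parse structure line for entry: ", name)
    out[[length(out) + 1L]] <-
      parseDotBracket(seq, m[2], energy = as.numeric(m[3]), name = name)
    i <- i + 2L
  }
  out
}

#' Screening thresholds for aptamer-likeness
#'
#' A structure counts as aptamer-like when it is stable and well-paired:
#' energy density at or below `maxEnergyDensity`, unpaired fraction at or
#' below `maxUnpairedFraction`, at least `minHairpins` hairpin loop(s) and
#' a longest stem of at least `minLongestStem` stacked pairs.
#'
#' The default values are calibrated to the pseudo-energy scale of the
#' built-in base-pair-maximization folder ([nussinovFold()], energy =
#' -pairs), chosen so that canonical stem-loop structures pass while
#' weakly paired sequences fail, with both outcomes reachable by random
#' sequences at every aptamer-typical length (20-100 nt) — a property the
#' negative-set construction relies on. With a thermodynamic engine's
#' kcal/mol energies, `maxEnergyDensity` should be rescaled accordingly.
#'
#' @param maxEnergyDensity Energy per nucleotide at or below which a
#'   structure counts as stable (default -0.30 in pseudo-energy per nt,
#'   i.e. at least 30% of bases in pairs).
#' @param maxUnpairedFraction Maximum tolerated fraction of unpaired bases
#'   (default 0.38).
#' @param minHairpins Minimum hairpin-loop count (default 1).
#' @param minLongestStem Minimum length of the longest stem (default 4).
#' @return A list of class `screeningThresholds`.
#' @export
screeningThresholds <- function(maxEnergyDensity = -0.30,
                                maxUnpairedFraction = 0.38,
                                minHairpins = 1, minLongestStem = 4) {
  stopifnot(is.finite(maxEnergyDensity), is.finite(maxUnpairedFraction),
            minHairpins >= 0, minLongestStem >= 0)
  structure(list(maxEnergyDensity = maxEnergyDensity,
                 maxUnpairedFraction = maxUnpairedFraction,
                 minHairpins = minHairpins,
                 minLongestStem = minLongestStem),
            class = "screeningThresholds")
}

#' Classify a structure as aptamer-like or not
#'
#' @param record A [StructureRecord-class].
#' @param thresholds A [screeningThresholds()] list.
#' @return `TRUE` when the record meets every aptamer-likeness condition.
#' @export
aptamerLikeness <- function(record, thresholds = screeningThresholds()) {
  stopifnot(is(record, "StructureRecord"),
            inherits(thresholds, "screeningThresholds"))
  s <- structureStats(record)
  s$energyDensity <= thresholds$maxEnergyDensity &&
    s$unpairedFraction <= thresholds$maxUnpairedFraction &&
    s$hairpinCount >= thresholds$minHairpins &&
    s$longestStem >= thresholds$minLongestStem
}

#' Generate a structure-screened negative aptamer set
#'
#' Draws `n` target lengths from the empirical length distribution of the
#' positive aptamers, then for each length rejection-samples sequences
#' with bases i.i.d. from the positives' mononucleotide frequencies until
#' one is *not* aptamer-like under the screening thresholds — mirroring
#' the construction in which random sequences that do not conform to the
#' structural pattern of aptamers become the negative class. Stratifying
#' by length first means the negatives' length distribution matches the
#' positives' exactly up to sampling noise, even though the rejection
#' probability varies with length.
#'
#' @param positives Positive aptamer sequences (character vector or
#'   XStringSet), all one molecule kind.
#' @param n Number of negatives to generate.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param thresholds A [screeningThresholds()] list.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param maxAttempts Attempt budget before giving up (default `50 * n`);
#'   exceeding it raises an error suggesting the thresholds admit too many
#'   aptamer-like candidates.
#' @return A `DNAStringSet` or `RNAStringSet` of `n` screened negatives;
#'   rejection statistics are attached as `metadata()` (`attempts`,
#'   `rejectedAptamerLike`) and reported via `message()`.
#' @export
generateNegatives <- function(positives, n, molecule = c("DNA", "RNA"),
                              thresholds = screeningThresholds(),
                              seed = NULL, maxAttempts = 50 * n) {
  molecule <- match.arg(molecule)
  stopifnot(n >= 1)
  positives <- .nucleotideSeqs(positives, molecule)
  if (!length(positives)) stop("empty positive set")
  lens <- nchar(positives)
  letters4 <- if (molecule == "DNA") DNA_LETTERS else RNA_LETTERS
  baseFreq <- tabulate(match(chartr("U", "T",
                                    unlist(strsplit(positives, ""))),
                             DNA_LETTERS), 4L)
  baseFreq <- baseFreq / sum(baseFreq)

  withSeed(seed, {
    targets <- sample(lens, n, replace = TRUE)
    accepted <- character(0)
    attempts <- 0L
    rejected <- 0L
    for (L in targets) {
      repeat {
        if (attempts >= maxAttempts) {
          stop(sprintf(
            "acceptance rate too low (%d accepted in %d attempts): %s",
            length(accepted), attempts,
            "screening thresholds reject too few aptamer-like candidates"))
        }
        attempts <- attempts + 1L
        cand <- paste(sample(letters4, L, replace = TRUE, prob = baseFreq),
                      collapse = "")
        rec <- nussinovFold(cand)
        if (!aptamerLikeness(rec, thresholds)) {
          accepted <- c(accepted, cand)
          break
        }
        rejected <- rejected + 1L
      }
    }
    names(accepted) <- sprintf("neg_%04d", seq_len(n))
    out <- if (molecule == "DNA") Biostrings::DNAStringSet(accepted)
           else Biostrings::RNAStringSet(accepted)
    S4Vectors::metadata(out) <- list(attempts = attempts,
                                     rejectedAptamerLike = rejected)
    message(sprintf(
      "generated %d negatives in %d attempts (%d aptamer-like rejected)",
      n, attempts, rejected))
    out
  })
}

#' Length statistics of a sequence set
#'
#' @param seqs Character vector or XStringSet.
#' @param lo,hi Window of interest in nucleotides (default 30-80).
#' @return A list with `mode` (most frequent length; smallest on ties),
#'   `fractionWithin` (fraction of lengths in `[lo, hi]`), and `histogram`
#'   (a table of length counts).
#' @export
lengthStats <- function(seqs, lo = 30, hi = 80) {
  seqs <- .asSeqChar(seqs)
  if (!length(seqs)) stop("empty sequence list")
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  list(mode = modal,
       fractionWithin = mean(lens >= lo & lens <= hi),
       histogram = tab)
}

#' Per-candidate screening report
#'
#' Folds each sequence and tabulates its screening statistics together
#' with the aptamer-likeness call.
#'
#' @param seqs Character vector or XStringSet of nucleotide sequences.
#' @param thresholds A [screeningThresholds()] list.
#' @param minLoop Minimum hairpin size for the built-in folder.
#' @return A data frame with one row per sequence: name, length, the
#'   structure statistics and `aptamerLike`.
#' @export
screeningReport <- function(seqs, thresholds = screeningThresholds(),
                            minLoop = 3) {
  seqs <- .asSeqChar(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    rec <- nussinovFold(seqs[[i]], minLoop = minLoop,
                        name = names(seqs)[i])
    s <- structureStats(rec)
    data.frame(name = names(seqs)[i], length = nchar(seqs[[i]]),
               pairCount = s$pairCount, hairpinCount = s$hairpinCount,
               bulgeCount = s$bulgeCount,
               internalLoopCount = s$internalLoopCount,
               stemCount = s$stemCount, longestStem = s$longestStem,
               unpairedFraction = s$unpairedFraction,
               energy = rec@energy, energyDensity = s$energyDensity,
               aptamerLike = aptamerLikeness(rec, thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
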