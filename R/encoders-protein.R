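## Protein feature encoders: AAC, GAAC, PseAAC (Chou type 1), CTD
## (composition by default; transition/distribution available but off by
## default), and the sequence-order-coupling number over two embedded
## distance matrices. Each encoder takes a character vector (or
## AAStringSet) and returns a numeric matrix with one row per sequence and
## named columns.

.proteinSeqs <- function(seqs) {
  seqs <- .asSeqChar(seqs)
  .checkAlphabet(seqs, AA_LETTERS, "protein")
  if (any(nchar(seqs) < 1L)) stop("zero-length protein sequence")
  seqs
}

.encodeMatrix <- function(seqs, dim, names, fun) {
  out <- matrix(NA_real_, nrow = length(seqs), ncol = dim,
                dimnames = list(names(seqs), names))
  for (i in seq_along(seqs)) out[i, ] <- fun(seqs[[i]])
  out
}

#' Amino acid composition (AAC)
#'
#' Frequency of each of the 20 amino acids; rows sum to 1.
#'
#' @param seqs Character vector or AAStringSet of protein sequences.
#' @return Numeric matrix, one row per sequence, 20 columns `AAC.A` ...
#'   `AAC.Y`.
#' @export
encodeAAC <- function(seqs) {
  seqs <- .proteinSeqs(seqs)
  .encodeMatrix(seqs, 20L, paste0("AAC.", AA_LETTERS), function(s) {
    ch <- strsplit(s, "")[[1]]
    tabulate(match(ch, AA_LETTERS), 20L) / length(ch)
  })
}

#' Grouped amino acid composition (GAAC)
#'
#' Frequency of residues in each of five physicochemical groups
#' (aliphatic, aromatic, positively charged, negatively charged,
#' uncharged); rows sum to 1.
#'
#' @inheritParams encodeAAC
#' @return Numeric matrix with 5 named columns.
#' @export
encodeGAAC <- function(seqs) {
  seqs <- .proteinSeqs(seqs)
  groups <- gaacGroups()
  lookup <- setNames(rep(seq_along(groups), lengths(groups)),
                     unlist(groups))
  .encodeMatrix(seqs, length(groups),
                paste0("GAAC.", names(groups)), function(s) {
    ch <- strsplit(s, "")[[1]]
    tabulate(lookup[ch], length(groups)) / length(ch)
  })
}

## Standardized AA property matrix (3 columns) for PseAAC's Theta
.paacProps <- function() {
  p <- aaProperties()
  z <- vapply(c("hydrophobicity", "hydrophilicity", "sidechain_mass"),
              function(col) .standardize(p[[col]]), numeric(20))
  rownames(z) <- AA_LETTERS
  z
}

#' Pseudo amino acid composition (PseAAC, type 1)
#'
#' The 20 amino-acid frequencies augmented with `lambda` sequence-order
#' correlation factors. The correlation function between residues is the
#' mean squared difference of their standardized hydrophobicity,
#' hydrophilicity and side-chain mass; the j-th factor averages it over
#' all residue pairs at separation j. Components are jointly normalized so
#' the full vector sums to 1.
#'
#' @inheritParams encodeAAC
#' @param lambda Maximum sequence separation (default 30); every sequence
#'   must be longer than `lambda`.
#' @param w Weight of the sequence-order terms (default 0.05).
#' @return Numeric matrix with `20 + lambda` named columns.
#' @export
encodePseAAC <- function(seqs, lambda = 30, w = 0.05) {
  stopifnot(lambda >= 1, w > 0)
  seqs <- .proteinSeqs(seqs)
  short <- nchar(seqs) <= lambda
  if (any(short)) {
    stop(sprintf("sequence(s) %s shorter than lambda + 1 = %d",
                 paste(names(seqs)[short], collapse = ", "), lambda + 1L))
  }
  z <- .paacProps()
  cn <- c(paste0("PseAAC.", AA_LETTERS),
          paste0("PseAAC.lambda", seq_len(lambda)))
  .encodeMatrix(seqs, 20L + lambda, cn, function(s) {
    idx <- match(strsplit(s, "")[[1]], AA_LETTERS)
    n <- length(idx)
    f <- tabulate(idx, 20L) / n
    zs <- z[idx, , drop = FALSE]
    theta <- vapply(seq_len(lambda), function(j) {
      d <- zs[seq_len(n - j), , drop = FALSE] -
        zs[(j + 1L):n, , drop = FALSE]
      mean(rowMeans(d^2))
    }, numeric(1))
    denom <- sum(f) + w * sum(theta)
    c(f, w * theta) / denom
  })
}

#' CTD composition (CTDC)
#'
#' For each of seven physicochemical attributes (hydrophobicity, van der
#' Waals volume, polarity, polarizability, charge, secondary structure,
#' solvent accessibility), the frequency of residues in each of three
#' attribute classes. Each attribute's triple sums to 1.
#'
#' @inheritParams encodeAAC
#' @return Numeric matrix with 21 named columns
#'   (`CTDC.<attribute>.G1..G3`).
#' @export
encodeCTDC <- function(seqs) {
  seqs <- .proteinSeqs(seqs)
  groups <- ctdGroups()
  lookups <- lapply(groups, function(g)
    setNames(rep(1:3, lengths(g)), unlist(g)))
  cn <- unlist(lapply(names(groups), function(p)
    paste0("CTDC.", p, ".G", 1:3)))
  .encodeMatrix(seqs, 21L, cn, function(s) {
    ch <- strsplit(s, "")[[1]]
    unlist(lapply(lookups, function(lk)
      tabulate(lk[ch], 3L) / length(ch)), use.names = FALSE)
  })
}

#' CTD transition (CTDT)
#'
#' Frequency of transitions between attribute classes among adjacent
#' residues, for the same seven attributes as [encodeCTDC()]. Not part of
#' the default protein feature set; exposed for completeness.
#'
#' @inheritParams encodeAAC
#' @return Numeric matrix with 21 named columns
#'   (`CTDT.<attribute>.G12/G13/G23`).
#' @export
encodeCTDT <- function(seqs) {
  seqs <- .proteinSeqs(seqs)
  if (any(nchar(seqs) < 2L)) stop("CTDT needs length >= 2")
  groups <- ctdGroups()
  lookups <- lapply(groups, function(g)
    setNames(rep(1:3, lengths(g)), unlist(g)))
  cn <- unlist(lapply(names(groups), function(p)
    paste0("CTDT.", p, c(".G12", ".G13", ".G23"))))
  .encodeMatrix(seqs, 21L, cn, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    unlist(lapply(lookups, function(lk) {
      a <- lk[ch[-n]]; b <- lk[ch[-1]]
      c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
        sum((a == 1 & b == 3) | (a == 3 & b == 1)),
        sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (n - 1)
    }), use.names = FALSE)
  })
}

#' CTD distribution (CTDD)
#'
#' For each attribute class, the relative sequence positions (as a
#' fraction of length) at which the first, 25%, 50%, 75% and last residue
#' of that class occur (0 when the class is absent). Not part of the
#' default protein feature set.
#'
#' @inheritParams encodeAAC
#' @return Numeric matrix with 105 named columns.
#' @export
encodeCTDD <- function(seqs) {
  seqs <- .proteinSeqs(seqs)
  groups <- ctdGroups()
  lookups <- lapply(groups, function(g)
    setNames(rep(1:3, lengths(g)), unlist(g)))
  qs <- c(1, 25, 50, 75, 100)
  cn <- unlist(lapply(names(groups), function(p)
    unlist(lapply(1:3, function(g)
      paste0("CTDD.", p, ".G", g, ".P", qs)))))
  .encodeMatrix(seqs, 105L, cn, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    unlist(lapply(lookups, function(lk) {
      cls <- lk[ch]
      unlist(lapply(1:3, function(g) {
        pos <- which(cls == g)
        if (!length(pos)) return(numeric(5))
        ranks <- pmax(1L, ceiling(qs / 100 * length(pos)))
        pos[ranks] / n
      }))
    }), use.names = FALSE)
  })
}

#' Sequence-order-coupling number (SOCN)
#'
#' For each distance matrix and each separation d in 1..lambda, the sum of
#' squared physicochemical distances between residues d apart:
#' \eqn{f_d = \sum_{i=1}^{N-d} d(R_i, R_{i+d})^2}. Two matrices are used:
#' the package's composite physicochemical matrix (see [physchemMatrix()])
#' followed by the Grantham chemical matrix.
#'
#' @inheritParams encodeAAC
#' @param lambda Maximum separation (default 30); sequences must be longer
#'   than `lambda`.
#' @return Numeric matrix with `2 * lambda` named columns
#'   (`SOCN.physchem.d1..`, `SOCN.grantham.d1..`).
#' @export
encodeSOCN <- function(seqs, lambda = 30) {
  stopifnot(lambda >= 1)
  seqs <- .proteinSeqs(seqs)
  short <- nchar(seqs) <= lambda
  if (any(short)) {
    stop(sprintf("sequence(s) %s too short for SOCN: minimum length is %d",
                 paste(names(seqs)[short], collapse = ", "), lambda + 1L))
  }
  mats <- list(physchem = physchemMatrix(), grantham = granthamMatrix())
  cn <- unlist(lapply(names(mats), function(m)
    paste0("SOCN.", m, ".d", seq_len(lambda))))
  .encodeMatrix(seqs, 2L * lambda, cn, function(s) {
    idx <- match(strsplit(s, "")[[1]], AA_LETTERS)
    n <- length(idx)
    unlist(lapply(mats, function(M) {
      vapply(seq_len(lambda), function(d) {
        i <- seq_len(n - d)
        sum(M[cbind(idx[i], idx[i + d])]^2)
      }, numeric(1))
    }), use.names = FALSE)
  })
}

#' Protein encoder configuration
#'
#' @param encoders Ordered subset of
#'   `c("AAC", "PseAAC", "GAAC", "CTDC", "SOCN")`; optionally `"CTDT"` and
#'   `"CTDD"` may be added.
#' @param pseaacLambda,pseaacW PseAAC parameters.
#' @param socnLambda SOCN maximum separation.
#' @return A list of class `proteinEncoderConfig`.
#' @export
proteinEncoderConfig <- function(encoders = c("AAC", "PseAAC", "GAAC",
                                              "CTDC", "SOCN"),
                                 pseaacLambda = 30, pseaacW = 0.05,
                                 socnLambda = 30) {
  known <- c("AAC", "PseAAC", "GAAC", "CTDC", "SOCN", "CTDT", "CTDD")
  if (length(encoders) == 0L) stop("empty encoder configuration")
  bad <- setdiff(encoders, known)
  if (length(bad)) stop("unknown protein encoder(s): ",
                        paste(bad, collapse = ", "))
  structure(list(encoders = encoders, pseaacLambda = pseaacLambda,
                 pseaacW = pseaacW, socnLambda = socnLambda),
            class = "proteinEncoderConfig")
}

#' Encode proteins with a configurable set of encoders
#'
#' Concatenates the selected encoders in their declared order; with the
#' default configuration a sequence longer than 30 residues yields
#' 20 + 50 + 5 + 21 + 60 = 156 components.
#'
#' @inheritParams encodeAAC
#' @param config A [proteinEncoderConfig()].
#' @return Numeric matrix, one row per sequence, encoder-prefixed column
#'   names.
#' @export
encodeProtein <- function(seqs, config = proteinEncoderConfig()) {
  stopifnot(inherits(config, "proteinEncoderConfig"))
  blocks <- lapply(config$encoders, function(e) {
    switch(e,
           AAC = encodeAAC(seqs),
           PseAAC = encodePseAAC(seqs, lambda = config$pseaacLambda,
                                 w = config$pseaacW),
           GAAC = encodeGAAC(seqs),
           CTDC = encodeCTDC(seqs),
           SOCN = encodeSOCN(seqs, lambda = config$socnLambda),
           CTDT = encodeCTDT(seqs),
           CTDD = encodeCTDD(seqs))
  })
  do.call(cbind, blocks)
}
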