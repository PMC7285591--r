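## Nucleotide feature encoders: NAC, PseKNC (Chen's type-1 pseudo k-tuple
## composition) and the normalized Moreau-Broto autocorrelation, over
## molecule-specific dinucleotide property tables. DNA and RNA use
## different tables, so the molecule kind is an explicit argument and
## mismatched input is an error, never a silent coercion.

.nucleotideSeqs <- function(seqs, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  seqs <- .asSeqChar(seqs)
  letters4 <- if (molecule == "DNA") DNA_LETTERS else RNA_LETTERS
  wrong <- if (molecule == "DNA") "U" else "T"
  offending <- grepl(wrong, seqs, fixed = TRUE)
  if (any(offending)) {
    stop(sprintf("%s configuration applied to sequence(s) containing %s: %s",
                 molecule, wrong,
                 paste(names(seqs)[offending], collapse = ", ")))
  }
  .checkAlphabet(seqs, letters4, molecule)
  seqs
}

## Canonical 4-letter index: U is treated as the 4th base alongside T so
## DNA and RNA share one index space.
.baseIndex <- function(s) {
  match(chartr("U", "T", strsplit(s, "")[[1]]), DNA_LETTERS)
}

#' Nucleotide composition (NAC)
#'
#' Frequency of A, C, G and T/U (U counts in the T/U slot); rows sum to 1.
#'
#' @param seqs Character vector or XStringSet of nucleotide sequences.
#' @param molecule `"DNA"` or `"RNA"`.
#' @return Numeric matrix with columns `NAC.A`, `NAC.C`, `NAC.G`,
#'   `NAC.TU`.
#' @export
encodeNAC <- function(seqs, molecule = c("DNA", "RNA")) {
  seqs <- .nucleotideSeqs(seqs, molecule)
  .encodeMatrix(seqs, 4L, c("NAC.A", "NAC.C", "NAC.G", "NAC.TU"),
                function(s) {
    idx <- .baseIndex(s)
    tabulate(idx, 4L) / length(idx)
  })
}

## Dinucleotide index (1..16) at each of the L-1 positions
.dinucIndex <- function(s) {
  idx <- .baseIndex(s)
  n <- length(idx)
  if (n < 2L) stop("sequence too short for dinucleotides")
  (idx[-n] - 1L) * 4L + idx[-1L]
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' Normalized k-tuple frequencies augmented with `lambda` sequence-order
#' correlation factors computed from the standardized dinucleotide property
#' table of the declared molecule: the correlation between two positions
#' is the mean squared difference of their dinucleotides' 11 standardized
#' property values, and the j-th factor averages it over all dinucleotide
#' pairs at separation j. The full vector sums to 1.
#'
#' @inheritParams encodeNAC
#' @param k Tuple size (default 2).
#' @param lambda Number of correlation factors (default 10); sequences
#'   must satisfy `L - 1 > lambda`.
#' @param w Weight of the correlation terms (default 0.05).
#' @return Numeric matrix with `4^k + lambda` named columns.
#' @export
encodePseKNC <- function(seqs, k = 2, lambda = 10, w = 0.05,
                         molecule = c("DNA", "RNA")) {
  stopifnot(k >= 1, lambda >= 1, w > 0)
  molecule <- match.arg(molecule)
  seqs <- .nucleotideSeqs(seqs, molecule)
  L <- nchar(seqs)
  short <- L < k | (L - 1L) <= lambda
  if (any(short)) {
    stop(sprintf("sequence(s) %s too short for k = %d, lambda = %d",
                 paste(names(seqs)[short], collapse = ", "), k, lambda))
  }
  props <- dinucProperties(molecule)        # standardized 16 x 11
  letters4 <- if (molecule == "DNA") DNA_LETTERS else RNA_LETTERS
  tuples <- letters4
  if (k > 1) for (i in seq_len(k - 1)) {
    tuples <- as.vector(t(outer(tuples, letters4, paste0)))
  }
  cn <- c(paste0("PseKNC.", tuples),
          paste0("PseKNC.lambda", seq_len(lambda)))
  .encodeMatrix(seqs, 4L^k + lambda, cn, function(s) {
    idx <- .baseIndex(s)
    n <- length(idx)
    ktup <- idx[seq_len(n - k + 1L)]
    if (k > 1) for (i in seq_len(k - 1)) {
      ktup <- (ktup - 1L) * 4L + idx[(1L + i):(n - k + i + 1L)]
    }
    f <- tabulate(ktup, 4L^k) / (n - k + 1L)
    di <- .dinucIndex(s)
    m <- length(di)
    P <- props[di, , drop = FALSE]
    theta <- vapply(seq_len(lambda), function(j) {
      d <- P[seq_len(m - j), , drop = FALSE] - P[(j + 1L):m, , drop = FALSE]
      mean(rowMeans(d^2))
    }, numeric(1))
    denom <- sum(f) + w * sum(theta)
    c(f, w * theta) / denom
  })
}

#' Normalized Moreau-Broto autocorrelation (NMBAC)
#'
#' For each of the 11 dinucleotide properties p and each lag d in
#' 1..`maxLag`, the mean product of the standardized property profile with
#' itself at offset d along the sequence's L-1 dinucleotide positions:
#' \eqn{AC(p,d) = \frac{1}{L-1-d}\sum_i \tilde P_p(i)\,\tilde P_p(i+d)}.
#'
#' @inheritParams encodeNAC
#' @param maxLag Largest lag (default 10); sequences must satisfy
#'   `L - 1 > maxLag`.
#' @return Numeric matrix with `11 * maxLag` named columns
#'   (`NMBAC.<property>.lag<d>`).
#' @export
encodeNMBAC <- function(seqs, maxLag = 10, molecule = c("DNA", "RNA")) {
  stopifnot(maxLag >= 1)
  molecule <- match.arg(molecule)
  seqs <- .nucleotideSeqs(seqs, molecule)
  short <- (nchar(seqs) - 1L) <= maxLag
  if (any(short)) {
    stop(sprintf("sequence(s) %s too short for maxLag = %d (need L - 1 > maxLag)",
                 paste(names(seqs)[short], collapse = ", "), maxLag))
  }
  props <- dinucProperties(molecule)
  pn <- colnames(props)
  cn <- unlist(lapply(pn, function(p)
    paste0("NMBAC.", p, ".lag", seq_len(maxLag))))
  .encodeMatrix(seqs, ncol(props) * maxLag, cn, function(s) {
    di <- .dinucIndex(s)
    m <- length(di)
    P <- props[di, , drop = FALSE]
    unlist(lapply(seq_len(ncol(P)), function(pi) {
      x <- P[, pi]
      vapply(seq_len(maxLag), function(d)
        mean(x[seq_len(m - d)] * x[(d + 1L):m]), numeric(1))
    }), use.names = FALSE)
  })
}

#' Nucleotide encoder configuration
#'
#' @param molecule `"DNA"` or `"RNA"`; every encoded sequence set must
#'   match.
#' @param encoders Ordered subset of `c("NAC", "PseKNC", "NMBAC")`.
#' @param psekncK,psekncLambda,psekncW PseKNC parameters.
#' @param nmbacMaxLag NMBAC largest lag.
#' @return A list of class `nucleotideEncoderConfig`.
#' @export
nucleotideEncoderConfig <- function(molecule = c("DNA", "RNA"),
                                    encoders = c("NAC", "PseKNC", "NMBAC"),
                                    psekncK = 2, psekncLambda = 10,
                                    psekncW = 0.05, nmbacMaxLag = 10) {
  molecule <- match.arg(molecule)
  known <- c("NAC", "PseKNC", "NMBAC")
  if (length(encoders) == 0L) stop("empty encoder configuration")
  bad <- setdiff(encoders, known)
  if (length(bad)) stop("unknown nucleotide encoder(s): ",
                        paste(bad, collapse = ", "))
  structure(list(molecule = molecule, encoders = encoders,
                 psekncK = psekncK, psekncLambda = psekncLambda,
                 psekncW = psekncW, nmbacMaxLag = nmbacMaxLag),
            class = "nucleotideEncoderConfig")
}

#' Encode nucleotide sequences with a configurable set of encoders
#'
#' Concatenates the selected encoders in declared order; the default
#' configuration yields 4 + 26 + 110 = 140 components.
#'
#' @inheritParams encodeNAC
#' @param config A [nucleotideEncoderConfig()]; its molecule kind must
#'   match the sequences.
#' @return Numeric matrix with encoder-prefixed column names.
#' @export
encodeNucleotide <- function(seqs, config = nucleotideEncoderConfig("DNA")) {
  stopifnot(inherits(config, "nucleotideEncoderConfig"))
  blocks <- lapply(config$encoders, function(e) {
    switch(e,
           NAC = encodeNAC(seqs, molecule = config$molecule),
           PseKNC = encodePseKNC(seqs, k = config$psekncK,
                                 lambda = config$psekncLambda,
                                 w = config$psekncW,
                                 molecule = config$molecule),
           NMBAC = encodeNMBAC(seqs, maxLag = config$nmbacMaxLag,
                               molecule = config$molecule))
  })
  do.call(cbind, blocks)
}
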