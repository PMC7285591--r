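# Independent oracle implementations: plain double-loop / recursive
# evaluations of each statistic, kept deliberately separate from the
# package's vectorized implementations. They share only the embedded data
# tables (which are data, not computation).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

zscore20 <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# Chou-style pseudo amino acid composition, term by term
oraclePseAAC <- function(s, lambda, w) {
  p <- aaProperties()
  z <- sapply(c("hydrophobicity", "hydrophilicity", "sidechain_mass"),
              function(col) zscore20(p[[col]]))
  rownames(z) <- AA20
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  f <- sapply(AA20, function(a) sum(ch == a) / n)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(n - j)) {
      d <- z[ch[i], ] - z[ch[i + j], ]
      acc <- acc + mean(d^2)
    }
    theta[j] <- acc / (n - j)
  }
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

# Sequence-order-coupling numbers by explicit double loop
oracleSOCN <- function(s, lambda) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  out <- numeric(0)
  for (M in list(physchemMatrix(), granthamMatrix())) {
    for (d in seq_len(lambda)) {
      acc <- 0
      for (i in seq_len(n - d)) acc <- acc + M[ch[i], ch[i + d]]^2
      out <- c(out, acc)
    }
  }
  out
}

# Pseudo k-tuple nucleotide composition, term by term
oraclePseKNC <- function(s, k, lambda, w, molecule = "DNA") {
  props <- dinucProperties(molecule)
  ch <- strsplit(chartr("U", "T", s), "")[[1]]
  n <- length(ch)
  letters4 <- c("A", "C", "G", "T")
  tuples <- letters4
  if (k > 1) for (i in seq_len(k - 1)) {
    tuples <- as.vector(t(outer(tuples, letters4, paste0)))
  }
  kmers <- vapply(seq_len(n - k + 1),
                  function(i) paste(ch[i:(i + k - 1)], collapse = ""),
                  character(1))
  f <- sapply(tuples, function(u) sum(kmers == u) / length(kmers))
  dinucs <- vapply(seq_len(n - 1),
                   function(i) paste(ch[i:(i + 1)], collapse = ""),
                   character(1))
  dnames <- as.vector(t(outer(letters4, letters4, paste0)))
  rownames(props) <- chartr("U", "T", rownames(props))
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    m <- length(dinucs)
    acc <- 0
    for (i in seq_len(m - j)) {
      d <- props[dinucs[i], ] - props[dinucs[i + j], ]
      acc <- acc + mean(d^2)
    }
    theta[j] <- acc / (m - j)
  }
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

# Normalized Moreau-Broto autocorrelation by explicit double loop
oracleNMBAC <- function(s, maxLag, molecule = "DNA") {
  props <- dinucProperties(molecule)
  rownames(props) <- chartr("U", "T", rownames(props))
  ch <- strsplit(chartr("U", "T", s), "")[[1]]
  n <- length(ch)
  dinucs <- vapply(seq_len(n - 1),
                   function(i) paste(ch[i:(i + 1)], collapse = ""),
                   character(1))
  out <- numeric(0)
  for (pn in colnames(props)) {
    x <- props[dinucs, pn]
    for (d in seq_len(maxLag)) {
      acc <- 0
      m <- length(x)
      for (i in seq_len(m - d)) acc <- acc + x[i] * x[i + d]
      out <- c(out, unname(acc) / (m - d))
    }
  }
  out
}

# Exhaustive maximum-base-pair count by plain recursion (no memoization):
# every nested pairing is explored.
canPairChr <- function(a, b) {
  if (a == "T") a <- "U"
  if (b == "T") b <- "U"
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

oracleMaxPairs <- function(s, minLoop = 3) {
  ch <- strsplit(toupper(s), "")[[1]]
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + 1L, j)) {
      if (k - i > minLoop && canPairChr(ch[i], ch[k])) {
        cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (cand > best) best <- cand
      }
    }
    best
  }
  rec(1L, length(ch))
}

# AUC by counting concordant positive/negative pairs (+ half ties)
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

randomProteinSeq <- function(L) paste(sample(AA20, L, TRUE), collapse = "")
randomDnaSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                  collapse = "")
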