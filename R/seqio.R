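## FASTA and pair-table I/O, alphabet validation, and the
## problematic-sequence filter applied before any dataset is assembled.

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file leniently: headers are truncated at the
#' first whitespace, wrapped and unwrapped bodies are both accepted, and
#' residues are upper-cased. No alphabet check is performed at this stage so
#' that problematic records (ambiguity codes, mixed U/T) can still be read
#' and then rejected explicitly by [filterProblematic()] or
#' [validateAlphabet()].
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences.
#' @seealso [writeFasta()], [filterProblematic()], [validateAlphabet()]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for entry: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector or XStringSet.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
  seqs <- .asSeqChar(seqs)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Drop problematic sequences
#'
#' Partitions a set of sequences into kept and discarded records. A
#' sequence is discarded when it contains the letter `B`, the letter `N`,
#' or a mixture of `U` and `T` — the records that cannot be encoded
#' unambiguously as a single nucleotide alphabet. The filter targets
#' nucleotide records; set `includeProtein = TRUE` to apply the same rule
#' to protein input (where `B` is the ambiguous Asx code).
#'
#' @param seqs Named character vector or XStringSet.
#' @param includeProtein Apply the filter even though the records are
#'   proteins? Default `FALSE` (nucleotide semantics).
#' @return A list with `kept` (named character vector) and `discarded`
#'   (data frame with columns `name`, `reason`).
#' @export
filterProblematic <- function(seqs, includeProtein = FALSE) {
  seqs <- .asSeqChar(seqs)
  reason <- character(length(seqs))
  hasB <- grepl("B", seqs, fixed = TRUE)
  hasN <- grepl("N", seqs, fixed = TRUE)
  mixedUT <- grepl("U", seqs, fixed = TRUE) & grepl("T", seqs, fixed = TRUE)
  reason[mixedUT] <- "mixed U/T"
  reason[hasN] <- "contains N"
  reason[hasB] <- "contains B"
  drop <- nzchar(reason)
  list(
    kept = seqs[!drop],
    discarded = data.frame(name = names(seqs)[drop],
                           reason = reason[drop],
                           stringsAsFactors = FALSE)
  )
}

#' Validate sequences against a strict molecule alphabet
#'
#' Coerces a set of sequences to the Biostrings container for the declared
#' molecule, rejecting any record with letters outside the strict canonical
#' alphabet (20 amino acids; ACGT; ACGU). Rejecting rather than skipping is
#' deliberate: silently dropping residues would change sequence length and
#' corrupt every frequency-based feature downstream.
#'
#' @param seqs Named character vector or XStringSet.
#' @param molecule `"protein"`, `"DNA"` or `"RNA"`.
#' @return An `AAStringSet`, `DNAStringSet` or `RNAStringSet`.
#' @export
validateAlphabet <- function(seqs, molecule = c("protein", "DNA", "RNA")) {
  molecule <- match.arg(molecule)
  seqs <- .asSeqChar(seqs)
  letters <- switch(molecule, protein = AA_LETTERS, DNA = DNA_LETTERS,
                    RNA = RNA_LETTERS)
  .checkAlphabet(seqs, letters, molecule)
  switch(molecule,
         protein = Biostrings::AAStringSet(seqs),
         DNA = Biostrings::DNAStringSet(seqs),
         RNA = Biostrings::RNAStringSet(seqs))
}

#' Load a protein-aptamer pair dataset from delimited text
#'
#' Reads a pair table (one row per protein-aptamer pair) with configurable
#' column mapping and coerces labels to 0/1. Accepted positive label
#' tokens: `1`, `yes`, `interacting`, `positive`, `true`; negative tokens:
#' `0`, `no`, `non-interacting`, `negative`, `false` (case-insensitive).
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param columns Named character vector mapping the required roles
#'   `protein_id`, `protein_seq`, `aptamer_id`, `aptamer_seq`, `label` to
#'   column names in the file.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @return A data frame with columns `protein_id`, `protein_seq`,
#'   `aptamer_id`, `aptamer_seq`, `label` (integer 0/1); sequences
#'   upper-cased.
#' @export
loadPairDataset <- function(path,
                            columns = c(protein_id = "protein_id",
                                        protein_seq = "protein_seq",
                                        aptamer_id = "aptamer_id",
                                        aptamer_seq = "aptamer_seq",
                                        label = "label"),
                            sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- c("protein_id", "protein_seq", "aptamer_id", "aptamer_seq",
                "label")
  if (!all(required %in% names(columns))) {
    stop("column mapping must name: ", paste(required, collapse = ", "))
  }
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns[required]), names(df))
  if (length(missing)) {
    stop("pair table lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    protein_id = as.character(df[[columns[["protein_id"]]]]),
    protein_seq = toupper(as.character(df[[columns[["protein_seq"]]]])),
    aptamer_id = as.character(df[[columns[["aptamer_id"]]]]),
    aptamer_seq = toupper(as.character(df[[columns[["aptamer_seq"]]]])),
    label = NA_integer_,
    stringsAsFactors = FALSE
  )
  tok <- tolower(trimws(as.character(df[[columns[["label"]]]])))
  pos <- c("1", "yes", "interacting", "positive", "true")
  neg <- c("0", "no", "non-interacting", "negative", "false")
  out$label[tok %in% pos] <- 1L
  out$label[tok %in% neg] <- 0L
  bad <- which(is.na(out$label))
  if (length(bad)) {
    stop(sprintf("unknown label token '%s' in row %d", tok[bad[1]], bad[1]))
  }
  empty <- which(!nzchar(out$protein_seq) | !nzchar(out$aptamer_seq))
  if (length(empty)) stop("empty sequence in row ", empty[1])
  out
}

#' Apply the problematic-sequence filter to a pair dataset
#'
#' Drops pairs whose aptamer sequence contains `B`, `N`, or both `U` and
#' `T` (see [filterProblematic()]).
#'
#' @param pairs Data frame from [loadPairDataset()].
#' @return A list with `kept` (filtered data frame) and `discarded`
#'   (data frame with `name`, `reason`).
#' @export
filterPairDataset <- function(pairs) {
  apt <- setNames(pairs$aptamer_seq, pairs$aptamer_id)
  flt <- filterProblematic(apt)
  keep <- !nzchar(.reasonFor(pairs$aptamer_seq))
  list(kept = pairs[keep, , drop = FALSE], discarded = flt$discarded)
}

.reasonFor <- function(seqs) {
  reason <- character(length(seqs))
  reason[grepl("U", seqs, fixed = TRUE) &
           grepl("T", seqs, fixed = TRUE)] <- "mixed U/T"
  reason[grepl("N", seqs, fixed = TRUE)] <- "contains N"
  reason[grepl("B", seqs, fixed = TRUE)] <- "contains B"
  reason
}

#' Write a discard report
#'
#' @param discarded Data frame with `name` and `reason` columns.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeDiscardReport <- function(discarded, path) {
  write.table(discarded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
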