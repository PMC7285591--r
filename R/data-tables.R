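## Embedded data resources: amino-acid property scales, CTD/GAAC groupings,
## distance matrices for the sequence-order-coupling number, and the
## dinucleotide physicochemical tables behind PseKNC/NMBAC.
## All are parsed once per session and cached.

.table_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, envir = .table_cache)) {
    assign(key, build(), envir = .table_cache)
  }
  get(key, envir = .table_cache)
}

#' Amino-acid property scales used by the pseudo amino acid encoder
#'
#' Hydrophobicity, hydrophilicity and side-chain mass for the 20 canonical
#' amino acids, as a data frame keyed by single-letter code.
#'
#' @return A data frame with columns `aa`, `hydrophobicity`,
#'   `hydrophilicity`, `sidechain_mass`.
#' @export
aaProperties <- function() {
  .cached("aa_props", function() {
    df <- read.delim(.extdata("aa_properties.tsv"), comment.char = "#")
    stopifnot(identical(sort(df$aa), sort(AA_LETTERS)))
    df[match(AA_LETTERS, df$aa), , drop = FALSE]
  })
}

#' Five-group amino-acid partition for grouped amino acid composition
#'
#' @return Named list of character vectors partitioning the 20 letters into
#'   aliphatic, aromatic, positively charged, negatively charged and
#'   uncharged groups.
#' @export
gaacGroups <- function() {
  .cached("gaac", function() {
    df <- read.delim(.extdata("gaac_groups.tsv"), comment.char = "#")
    groups <- lapply(df$letters, function(s) strsplit(s, "")[[1]])
    names(groups) <- df$group
    stopifnot(identical(sort(unname(unlist(groups))), sort(AA_LETTERS)))
    groups
  })
}

#' Three-class groupings for the seven CTD attributes
#'
#' @return Named list (one element per physicochemical attribute) of
#'   3-element lists of letter vectors.
#' @export
ctdGroups <- function() {
  .cached("ctd", function() {
    df <- read.delim(.extdata("ctd_groups.tsv"), comment.char = "#")
    out <- lapply(seq_len(nrow(df)), function(i) {
      g <- lapply(df[i, c("group1", "group2", "group3")],
                  function(s) strsplit(as.character(s), "")[[1]])
      stopifnot(identical(sort(unname(unlist(g))), sort(AA_LETTERS)))
      g
    })
    names(out) <- df$property
    out
  })
}

#' Grantham chemical distance matrix
#'
#' The 20x20 Grantham distance matrix computed from the published
#' composition/polarity/volume values with
#' \eqn{D_{ij} = \rho\sqrt{1.833\,\Delta c^2 + 0.1018\,\Delta p^2 +
#' 0.000399\,\Delta v^2}}, where \eqn{\rho} scales the mean off-diagonal
#' distance to 100.
#'
#' @return A symmetric 20x20 numeric matrix with zero diagonal, rows and
#'   columns named by amino-acid letter.
#' @export
granthamMatrix <- function() {
  .cached("grantham", function() {
    df <- read.delim(.extdata("grantham_properties.tsv"), comment.char = "#")
    df <- df[match(AA_LETTERS, df$aa), , drop = FALSE]
    dc <- outer(df$composition, df$composition, "-")
    dp <- outer(df$polarity, df$polarity, "-")
    dv <- outer(df$volume, df$volume, "-")
    raw <- sqrt(1.833 * dc^2 + 0.1018 * dp^2 + 0.000399 * dv^2)
    rho <- 100 / mean(raw[upper.tri(raw)])
    m <- rho * raw
    dimnames(m) <- list(AA_LETTERS, AA_LETTERS)
    m
  })
}

#' Composite physicochemical distance matrix
#'
#' A 20x20 amino-acid distance matrix constructed by this package as the
#' Euclidean distance over standardized hydrophobicity, hydrophilicity and
#' side-chain mass, rescaled to a maximum of 1. It serves as the
#' physicochemical counterpart to the Grantham chemical matrix in the
#' sequence-order-coupling number.
#'
#' @return A symmetric 20x20 numeric matrix in \[0, 1\] with zero diagonal.
#' @export
physchemMatrix <- function() {
  .cached("physchem", function() {
    p <- aaProperties()
    z <- vapply(c("hydrophobicity", "hydrophilicity", "sidechain_mass"),
                function(col) .standardize(p[[col]]), numeric(20))
    m <- as.matrix(dist(z))
    m <- m / max(m)
    dimnames(m) <- list(AA_LETTERS, AA_LETTERS)
    m
  })
}

#' Dinucleotide physicochemical property table
#'
#' Eleven properties (shift, slide, rise, tilt, roll, twist, stacking
#' energy, entropy, enthalpy, free energy, hydrophilicity) over the 16
#' dinucleotides, for DNA or RNA. The thermodynamic rows follow published
#' nearest-neighbor parameter sets; the remaining rows are representative
#' values compiled with this package (the resource files are marked
#' `synthetic`). DNA and RNA tables differ, which is why encodings of the
#' two molecule types are never interchangeable.
#'
#' @param molecule `"DNA"` or `"RNA"`.
#' @param standardized Standardize each property to mean 0, variance 1
#'   across the 16 dinucleotides (the form every encoder consumes)?
#' @return A 16 x 11 numeric matrix, rows named by dinucleotide (T for DNA,
#'   U for RNA), columns by property.
#' @export
dinucProperties <- function(molecule = c("DNA", "RNA"), standardized = TRUE) {
  molecule <- match.arg(molecule)
  key <- paste0("dinuc_", molecule, "_", standardized)
  .cached(key, function() {
    file <- sprintf("dinuc_properties_%s_synthetic.tsv", tolower(molecule))
    df <- read.delim(.extdata(file), comment.char = "#")
    letters4 <- if (molecule == "DNA") DNA_LETTERS else RNA_LETTERS
    dinucs <- as.vector(t(outer(letters4, letters4, paste0)))
    stopifnot(setequal(df$dinuc, dinucs))
    m <- as.matrix(df[match(dinucs, df$dinuc), -1, drop = FALSE])
    rownames(m) <- dinucs
    if (standardized) m <- apply(m, 2, .standardize)
    m
  })
}
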