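#' @importFrom methods new validObject is slot
#' @importFrom stats runif rnorm pnorm var sd dist setNames
#' @importFrom utils read.delim write.table head
NULL

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_LETTERS <- c("A", "C", "G", "T")
RNA_LETTERS <- c("A", "C", "G", "U")

#' Run an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals
#' never perturb the global random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Accept XStringSet or (named) character; return named character vector
.asSeqChar <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    out <- NULL
  }
  if (!is.null(out)) {
    if (is.null(names(out)) && length(out) > 0) {
      names(out) <- paste0("seq", seq_along(out))
    }
    return(out)
  }
  stop("expected a character vector or an XStringSet")
}

.checkAlphabet <- function(seqs, letters, what) {
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% letters),
                logical(1))
  if (any(bad)) {
    stop(sprintf("%s sequence(s) %s contain letters outside {%s}",
                 what, paste(utils::head(which(bad), 5), collapse = ", "),
                 paste(letters, collapse = "")))
  }
  invisible(TRUE)
}

## Standardize to mean 0, variance 1 using the population (1/n) variance,
## so that a table of n values has exactly unit variance in the 1/n sense.
.standardize <- function(x) {
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) return(x * 0)
  (x - mu) / sdev
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "aptaboost")
  if (!nzchar(path)) stop("missing package data resource: ", file)
  path
}
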