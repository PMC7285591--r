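## Central S4 classes: a labeled feature dataset with per-row provenance,
## the boosted random-forest model, and a parsed secondary-structure
## record.

#' LabeledDataset: feature matrix with binary labels and provenance
#'
#' Rows are samples (pairs or single sequences), columns are named
#' features. `provenance` distinguishes real rows from SMOTE-synthesized
#' ones so that synthetic rows can never leak into an evaluation.
#'
#' @slot features Numeric matrix with unique column names.
#' @slot labels Integer vector of 0/1 labels, one per row.
#' @slot provenance Character vector, `"real"` or `"synthetic"` per row.
#' @export
setClass("LabeledDataset",
         representation(features = "matrix", labels = "integer",
                        provenance = "character"))

setValidity("LabeledDataset", function(object) {
  msgs <- character()
  n <- nrow(object@features)
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels length must equal feature row count")
  if (length(object@provenance) != n)
    msgs <- c(msgs, "provenance length must equal feature row count")
  if (!all(object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0/1")
  if (!all(object@provenance %in% c("real", "synthetic")))
    msgs <- c(msgs, "provenance must be 'real' or 'synthetic'")
  if (is.null(colnames(object@features)) ||
      anyDuplicated(colnames(object@features)))
    msgs <- c(msgs, "features must have unique column names")
  if (n > 0 && !all(is.finite(object@features)))
    msgs <- c(msgs, "features must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledDataset
#'
#' @param features Numeric matrix with named columns.
#' @param labels 0/1 vector (numeric or integer), one per row.
#' @param provenance Per-row provenance (`"real"`/`"synthetic"`);
#'   defaults to all-real.
#' @return A [LabeledDataset-class] object.
#' @export
labeledDataset <- function(features, labels,
                           provenance = rep("real", nrow(features))) {
  new("LabeledDataset", features = as.matrix(features),
      labels = as.integer(labels), provenance = as.character(provenance))
}

#' @describeIn LabeledDataset-class Feature matrix accessor.
#' @param x A `LabeledDataset`.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "LabeledDataset"))
  x@features
}

#' @describeIn LabeledDataset-class Label accessor (integer 0/1).
#' @export
sampleLabels <- function(x) {
  stopifnot(is(x, "LabeledDataset"))
  x@labels
}

#' @describeIn LabeledDataset-class Provenance accessor.
#' @export
sampleProvenance <- function(x) {
  stopifnot(is(x, "LabeledDataset"))
  x@provenance
}

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf(
    "LabeledDataset: %d samples x %d features (%d positive, %d synthetic)\n",
    nrow(object@features), ncol(object@features),
    sum(object@labels == 1L), sum(object@provenance == "synthetic")))
})

#' BoostedForestModel: AdaBoost ensemble of random forests
#'
#' Ordered base learners (random forests) with their AdaBoost weights and
#' the decision threshold used to turn scores into yes/no calls.
#'
#' @slot learners List of fitted `ranger` forests.
#' @slot alphas Numeric learner weights, one per learner.
#' @slot rounds Number of boosting rounds retained.
#' @slot learningRate Learning-rate multiplier applied to each weight.
#' @slot featureNames Training feature signature; prediction refuses
#'   mismatched input.
#' @slot threshold Decision threshold in (0, 1).
#' @slot params List of base-forest parameters (`nTrees`, `maxDepth`).
#' @export
setClass("BoostedForestModel",
         representation(learners = "list", alphas = "numeric",
                        rounds = "integer", learningRate = "numeric",
                        featureNames = "character", threshold = "numeric",
                        params = "list"))

setValidity("BoostedForestModel", function(object) {
  msgs <- character()
  if (object@rounds < 1L) msgs <- c(msgs, "at least one boosting round")
  if (length(object@learners) != length(object@alphas))
    msgs <- c(msgs, "one weight per learner")
  if (!all(is.finite(object@alphas)))
    msgs <- c(msgs, "learner weights must be finite")
  if (length(object@threshold) != 1 || object@threshold <= 0 ||
      object@threshold >= 1)
    msgs <- c(msgs, "threshold must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BoostedForestModel", function(object) {
  cat(sprintf(
    "BoostedForestModel: %d rounds (lr %.3g), forests of %d trees, %d features, threshold %.2f\n",
    object@rounds, object@learningRate, object@params$nTrees,
    length(object@featureNames), object@threshold))
})

#' StructureRecord: parsed secondary structure with screening statistics
#'
#' A dot-bracket structure together with its (pseudo-)energy and the loop
#' and stem statistics used by the aptamer-likeness screen.
#'
#' @slot name Sequence identifier.
#' @slot sequence Nucleotide sequence.
#' @slot dotbracket Balanced dot-bracket string of equal length.
#' @slot energy Folding energy (kcal/mol from an external engine, or the
#'   pseudo-energy `-pairCount` from the built-in folder).
#' @slot stats Named list: `pairCount`, `hairpinCount`, `bulgeCount`,
#'   `internalLoopCount`, `stemCount`, `longestStem`, `unpairedFraction`,
#'   `energyDensity`.
#' @export
setClass("StructureRecord",
         representation(name = "character", sequence = "character",
                        dotbracket = "character", energy = "numeric",
                        stats = "list"))

setValidity("StructureRecord", function(object) {
  msgs <- character()
  if (nchar(object@dotbracket) != nchar(object@sequence))
    msgs <- c(msgs, "dot-bracket length must equal sequence length")
  ch <- strsplit(object@dotbracket, "")[[1]]
  if (length(ch) && any(!ch %in% c("(", ")", ".")))
    msgs <- c(msgs, "dot-bracket may contain only '(', ')' and '.'")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    msgs <- c(msgs, "unbalanced dot-bracket")
  uf <- object@stats$unpairedFraction
  if (!is.null(uf) && (uf < 0 || uf > 1))
    msgs <- c(msgs, "unpaired fraction must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StructureRecord", function(object) {
  s <- object@stats
  cat(sprintf(
    "StructureRecord '%s': %d nt, %d pairs, %d hairpin(s), energy %.2f (density %.3f), unpaired %.2f\n",
    object@name, nchar(object@sequence), s$pairCount, s$hairpinCount,
    object@energy, s$energyDensity, s$unpairedFraction))
})

#' @describeIn StructureRecord-class Screening statistics accessor.
#' @param x A `StructureRecord`.
#' @export
structureStats <- function(x) {
  stopifnot(is(x, "StructureRecord"))
  x@stats
}

#' @describeIn StructureRecord-class Dot-bracket accessor.
#' @export
dotBracket <- function(x) {
  stopifnot(is(x, "StructureRecord"))
  x@dotbracket
}
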