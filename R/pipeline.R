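## End-to-end workflows: configuration, pair-feature assembly, training
## (with SMOTE on the training partition only), prediction tables, and a
## leakage-guarded evaluation entry point.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflows. Defaults follow
#' the published operating point where one exists: decision thresholds
#' 0.44 (pairs) and 0.48 (aptamers), forests of 10 trees with maximum
#' depth 150, 300 boosting rounds with learning rate 0.75, and the
#' default encoder parameters (PseAAC/SOCN lambda 30, PseKNC k = 2,
#' lambda = 10, NMBAC lag 10).
#'
#' SMOTE can only be applied to the training partition: requesting
#' test-set balancing is rejected here, at validation time.
#'
#' @param molecule Aptamer molecule kind, `"DNA"` or `"RNA"`.
#' @param proteinConfig A [proteinEncoderConfig()].
#' @param nucleotideConfig A [nucleotideEncoderConfig()]; its molecule
#'   must match `molecule`.
#' @param smoteK SMOTE neighbor count (default 5).
#' @param balance Balance the training partition with SMOTE (default
#'   `TRUE`)?
#' @param balanceTest Must be `FALSE`; present so that a configuration
#'   asking for test-set balancing fails loudly instead of silently.
#' @param boost A [boostParams()] list.
#' @param pairThreshold,aptamerThreshold Decision thresholds in (0, 1).
#' @param seed Default seed used by workflows when none is passed.
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(molecule = c("DNA", "RNA"),
                           proteinConfig = proteinEncoderConfig(),
                           nucleotideConfig = NULL,
                           smoteK = 5, balance = TRUE,
                           balanceTest = FALSE,
                           boost = boostParams(),
                           pairThreshold = 0.44,
                           aptamerThreshold = 0.48,
                           seed = NULL) {
  molecule <- match.arg(molecule)
  if (is.null(nucleotideConfig))
    nucleotideConfig <- nucleotideEncoderConfig(molecule)
  if (!identical(nucleotideConfig$molecule, molecule))
    stop("nucleotideConfig molecule does not match pipeline molecule")
  if (isTRUE(balanceTest))
    stop("balancing the test partition is not permitted: ",
         "SMOTE applies to the training set only")
  for (thr in c(pairThreshold, aptamerThreshold)) {
    if (thr <= 0 || thr >= 1) stop("thresholds must lie in (0, 1)")
  }
  structure(list(molecule = molecule, proteinConfig = proteinConfig,
                 nucleotideConfig = nucleotideConfig, smoteK = smoteK,
                 balance = balance, boost = boost,
                 pairThreshold = pairThreshold,
                 aptamerThreshold = aptamerThreshold, seed = seed),
            class = "pipelineConfig")
}

#' Assemble pair features
#'
#' Encodes each pair as the concatenation of its protein encoding and its
#' aptamer encoding. Unique sequences are encoded once and reused across
#' pairs.
#'
#' @param pairs Pair data frame (layout of [loadPairDataset()]).
#' @param config A [pipelineConfig()].
#' @return Numeric matrix, one row per pair.
#' @export
encodePairFeatures <- function(pairs, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  uprot <- unique(pairs$protein_seq)
  uapt <- unique(pairs$aptamer_seq)
  protFeat <- encodeProtein(setNames(uprot, uprot), config$proteinConfig)
  aptFeat <- encodeNucleotide(setNames(uapt, uapt),
                              config$nucleotideConfig)
  out <- cbind(protFeat[match(pairs$protein_seq, uprot), , drop = FALSE],
               aptFeat[match(pairs$aptamer_seq, uapt), , drop = FALSE])
  rownames(out) <- paste(pairs$aptamer_id, pairs$protein_id, sep = "|")
  out
}

.logStage <- function(fmt, ...) message(sprintf(fmt, ...))

#' Train the pair-interaction model
#'
#' Full training workflow: drop problematic aptamer sequences, encode
#' every pair (protein encoding followed by aptamer encoding), balance the
#' minority class with SMOTE (training partition only), and fit the
#' boosted random-forest classifier with the pair decision threshold.
#' Per-stage counts are reported via `message()`.
#'
#' @param pairs Pair data frame (layout of [loadPairDataset()]).
#' @param config A [pipelineConfig()].
#' @param seed Integer seed (falls back to `config$seed`).
#' @return A [BoostedForestModel-class].
#' @export
trainPairs <- function(pairs, config = pipelineConfig(), seed = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(seed)) seed <- config$seed
  flt <- filterPairDataset(pairs)
  .logStage("read %d pairs, discarded %d problematic", nrow(pairs),
            nrow(flt$discarded))
  pairs <- flt$kept
  if (length(unique(pairs$label)) < 2L)
    stop("training pairs must contain both classes")
  X <- encodePairFeatures(pairs, config)
  ds <- labeledDataset(X, pairs$label)
  .logStage("encoded %d pairs x %d features (%d positive, %d negative)",
            nrow(X), ncol(X), sum(pairs$label == 1L),
            sum(pairs$label == 0L))
  if (config$balance) {
    ds <- smote(ds, kNeighbors = config$smoteK, seed = seed)
    .logStage("after SMOTE: %d positive, %d negative (%d synthetic)",
              sum(sampleLabels(ds) == 1L), sum(sampleLabels(ds) == 0L),
              sum(sampleProvenance(ds) == "synthetic"))
  }
  model <- fitBoostedForest(ds, params = config$boost,
                            threshold = config$pairThreshold, seed = seed)
  .logStage("trained %d boosting round(s)", model@rounds)
  model
}

#' Predict all protein-aptamer pairs
#'
#' Scores every aptamer x protein combination and reports the documented
#' four-column table: aptamer name, protein name, yes/no result, score.
#'
#' @param model A [BoostedForestModel-class] trained by [trainPairs()].
#' @param proteins Named character vector or AAStringSet of proteins.
#' @param aptamers Named character vector or XStringSet of aptamers (one
#'   molecule kind; mixed U/T content across the set is rejected).
#' @param config The [pipelineConfig()] used in training.
#' @param threshold Decision threshold; defaults to the model's stored
#'   threshold.
#' @return Data frame with columns `aptamer`, `protein`, `result`,
#'   `score`, one row per combination.
#' @export
predictPairs <- function(model, proteins, aptamers,
                         config = pipelineConfig(),
                         threshold = model@threshold) {
  stopifnot(is(model, "BoostedForestModel"),
            inherits(config, "pipelineConfig"))
  proteins <- .asSeqChar(proteins)
  aptamers <- .asSeqChar(aptamers)
  if (!length(proteins)) stop("empty protein set")
  if (!length(aptamers)) stop("empty aptamer set")
  hasU <- any(grepl("U", aptamers, fixed = TRUE))
  hasT <- any(grepl("T", aptamers, fixed = TRUE))
  if (hasU && hasT)
    stop("aptamer file mixes DNA and RNA; predict the two separately")
  grid <- expand.grid(protein = names(proteins),
                      aptamer = names(aptamers),
                      stringsAsFactors = FALSE)
  pairs <- data.frame(protein_id = grid$protein,
                      protein_seq = unname(proteins[grid$protein]),
                      aptamer_id = grid$aptamer,
                      aptamer_seq = unname(aptamers[grid$aptamer]),
                      stringsAsFactors = FALSE)
  X <- encodePairFeatures(pairs, config)
  scores <- predictScore(model, X)
  data.frame(aptamer = pairs$aptamer_id, protein = pairs$protein_id,
             result = classifyScores(scores, threshold), score = scores,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Train the aptamer-prediction model
#'
#' Encodes known aptamers (positives) and structure-screened negatives
#' with the nucleotide encoders and fits the boosted forest with the
#' aptamer decision threshold (default 0.48). DNA and RNA must be trained
#' separately.
#'
#' @param positives,negatives Named character vectors or XStringSets of
#'   one molecule kind.
#' @param config A [pipelineConfig()].
#' @param seed Integer seed (falls back to `config$seed`).
#' @return A [BoostedForestModel-class].
#' @export
trainAptamer <- function(positives, negatives,
                         config = pipelineConfig(), seed = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(seed)) seed <- config$seed
  positives <- .asSeqChar(positives)
  negatives <- .asSeqChar(negatives)
  seqs <- c(positives, negatives)
  hasU <- any(grepl("U", seqs, fixed = TRUE))
  hasT <- any(grepl("T", seqs, fixed = TRUE))
  if (hasU && hasT)
    stop("DNA and RNA mixed in one aptamer training run; train separately")
  X <- encodeNucleotide(seqs, config$nucleotideConfig)
  ds <- labeledDataset(X, rep(c(1L, 0L), c(length(positives),
                                           length(negatives))))
  .logStage("encoded %d positives + %d negatives x %d features",
            length(positives), length(negatives), ncol(X))
  if (config$balance &&
      abs(length(positives) - length(negatives)) >= 2L) {
    ds <- smote(ds, kNeighbors = config$smoteK, seed = seed)
    .logStage("after SMOTE: %d/%d",
              sum(sampleLabels(ds) == 1L), sum(sampleLabels(ds) == 0L))
  }
  model <- fitBoostedForest(ds, params = config$boost,
                            threshold = config$aptamerThreshold,
                            seed = seed)
  .logStage("trained %d boosting round(s)", model@rounds)
  model
}

#' Predict aptamers from sequences
#'
#' @param model A [BoostedForestModel-class] trained by [trainAptamer()].
#' @param seqs Named character vector or XStringSet of nucleotide
#'   sequences (one molecule kind).
#' @param config The [pipelineConfig()] used in training.
#' @param threshold Decision threshold; defaults to the model's stored
#'   threshold.
#' @return Data frame with columns `name`, `result`, `score`.
#' @export
predictAptamer <- function(model, seqs, config = pipelineConfig(),
                           threshold = model@threshold) {
  stopifnot(is(model, "BoostedForestModel"),
            inherits(config, "pipelineConfig"))
  seqs <- .asSeqChar(seqs)
  X <- encodeNucleotide(seqs, config$nucleotideConfig)
  scores <- predictScore(model, X)
  data.frame(name = names(seqs),
             result = classifyScores(scores, threshold), score = scores,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate a model on real samples only
#'
#' Leakage guard: refuses any dataset containing SMOTE-synthesized rows,
#' then computes threshold metrics at the model's stored threshold plus
#' the ROC/AUC.
#'
#' @param model A [BoostedForestModel-class].
#' @param dataset A [LabeledDataset-class] of real samples.
#' @return A list with `metrics` (see [confusionMetrics()]), `roc` (see
#'   [rocCurve()]) and `scores`.
#' @export
evaluateModel <- function(model, dataset) {
  stopifnot(is(model, "BoostedForestModel"), is(dataset, "LabeledDataset"))
  if (any(sampleProvenance(dataset) == "synthetic"))
    stop("evaluation dataset contains synthetic rows; ",
         "evaluation must use real samples only")
  scores <- predictScore(model, featureMatrix(dataset))
  labels <- sampleLabels(dataset)
  preds <- as.integer(scores >= model@threshold)
  list(metrics = confusionMetrics(labels, preds),
       roc = rocCurve(labels, scores), scores = scores)
}

#' Look up records by name or exact sequence
#'
#' Convenience replacement for an interactive query page: searches a
#' user-supplied table (e.g. an aptamer or protein list) by identifier
#' substring or exact sequence match.
#'
#' @param table Data frame with at least `id` and `seq` columns (or a
#'   named character vector of sequences).
#' @param query Identifier substring or full sequence.
#' @return The matching rows as a data frame.
#' @export
lookupRecords <- function(table, query) {
  if (is.character(table)) {
    table <- data.frame(id = names(.asSeqChar(table)),
                        seq = unname(.asSeqChar(table)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(table)))
  hit <- grepl(query, table$id, fixed = TRUE) |
    table$seq == toupper(query)
  table[hit, , drop = FALSE]
}
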