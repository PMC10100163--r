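# Central S4 classes. Tabular per-molecule metadata travels as plain
# data.frames ("molecule record" tables: id, canonical_smiles,
# random_smiles, n_heavy, mw, has_stereo); model-side state is classed.

#' SmilesVocabulary
#'
#' Token vocabulary for the sequence model. The first four indices are
#' reserved for the padding, start-of-sequence, end-of-sequence and unknown
#' symbols; all remaining tokens map bijectively to indices.
#'
#' @slot tokens ordered character vector of tokens, reserved symbols first.
#' @export
setClass("SmilesVocabulary", representation(tokens = "character"))

.RESERVED_TOKENS <- c("<pad>", "<s>", "</s>", "<unk>")

setValidity("SmilesVocabulary", function(object) {
  if (length(object@tokens) < 4L ||
      !identical(object@tokens[1:4], .RESERVED_TOKENS))
    return("first four tokens must be the reserved symbols")
  if (anyDuplicated(object@tokens)) return("tokens must be unique")
  TRUE
})

#' SmilesCorpus
#'
#' A prepared translation corpus: molecule records, tokenized
#' random-to-canonical pairs with vocabulary indices, and length/stereo
#' bucket assignments.
#'
#' @slot records molecule record data.frame.
#' @slot source_ids list of integer vectors (randomized-SMILES tokens).
#' @slot target_ids list of integer vectors (canonical-SMILES tokens).
#' @slot bucket integer vector, one bucket id per pair.
#' @slot bucket_labels character vector naming each bucket id.
#' @slot vocabulary a \linkS4class{SmilesVocabulary}.
#' @export
setClass("SmilesCorpus", representation(
  records = "data.frame", source_ids = "list", target_ids = "list",
  bucket = "integer", bucket_labels = "character",
  vocabulary = "SmilesVocabulary"))

setValidity("SmilesCorpus", function(object) {
  n <- nrow(object@records)
  if (length(object@source_ids) != n || length(object@target_ids) != n ||
      length(object@bucket) != n)
    return("records, token lists and bucket vector must align")
  if (any(vapply(object@source_ids, length, 1L) == 0L) ||
      any(vapply(object@target_ids, length, 1L) == 0L))
    return("token sequences must be non-empty")
  TRUE
})

#' EDModel
#'
#' Parameter state of the GRU encoder-decoder: a 3-layer GRU encoder whose
#' concatenated final hidden states pass (with training-time Gaussian noise
#' and dropout) through a tanh bottleneck of `latent_dim` units; a decoder
#' that maps the latent vector through a tanh layer of `decoder_init_width`
#' units, split by layer width to initialize a 3-layer GRU emitting
#' per-step token distributions.
#'
#' @slot params named list of parameter matrices.
#' @slot config model configuration list (see [modelConfig()]).
#' @slot vocabulary the \linkS4class{SmilesVocabulary} the model speaks.
#' @slot max_decode_length integer decoding cap.
#' @export
setClass("EDModel", representation(
  params = "list", config = "list", vocabulary = "SmilesVocabulary",
  max_decode_length = "integer"))

#' CheckpointSet
#'
#' An ordered set of model snapshots taken at scheduled training epochs
#' ("various ED model set"). Display names are derived from each
#' snapshot's measured perfect accuracy ("Model_<acc%>"), not its epoch.
#'
#' @slot epochs strictly increasing integer epochs, first element 0.
#' @slot models list of \linkS4class{EDModel} snapshots.
#' @slot accuracy numeric measured perfect accuracies (NA until measured).
#' @slot loss_log data.frame of per-epoch mean training loss.
#' @export
setClass("CheckpointSet", representation(
  epochs = "integer", models = "list", accuracy = "numeric",
  loss_log = "data.frame"))

setValidity("CheckpointSet", function(object) {
  if (length(object@epochs) != length(object@models))
    return("one model per epoch")
  if (is.unsorted(object@epochs, strictly = TRUE))
    return("epochs must be strictly increasing")
  if (length(object@epochs) && object@epochs[1] != 0L)
    return("first checkpoint must be epoch 0 (untrained control)")
  TRUE
})

#' FidelityReport
#'
#' Per-checkpoint, per-evaluation-set translation fidelity: perfect
#' accuracy, partial accuracy and the fraction of decoded strings that are
#' valid SMILES, with replicate means and standard deviations.
#'
#' @slot table data.frame (checkpoint, epoch, eval_set, perfect, partial,
#'   validity).
#' @slot summary data.frame of replicate means and sds per checkpoint.
#' @export
setClass("FidelityReport", representation(
  table = "data.frame", summary = "data.frame"))

setValidity("FidelityReport", function(object) {
  tb <- object@table
  if (nrow(tb) && any(tb$partial + 1e-12 < tb$perfect))
    return("partial accuracy must be >= perfect accuracy on every row")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @describeIn SmilesVocabulary-class number of tokens (reserved included).
#' @param x object.
#' @export
setMethod("length", "SmilesVocabulary", function(x) length(x@tokens))

#' Vocabulary tokens
#' @param object a SmilesVocabulary.
#' @export
vocabTokens <- function(object) object@tokens

#' Molecule records of a corpus
#' @param object a SmilesCorpus.
#' @export
corpusRecords <- function(object) object@records

#' Vocabulary of a corpus or model
#' @param object a SmilesCorpus or EDModel.
#' @export
vocabulary <- function(object) object@vocabulary

#' Checkpoint epochs
#' @param object a CheckpointSet.
#' @export
checkpointEpochs <- function(object) object@epochs

#' Checkpoint model snapshots
#' @param object a CheckpointSet.
#' @export
checkpointModels <- function(object) object@models

#' Measured checkpoint accuracies
#' @param object a CheckpointSet.
#' @export
checkpointAccuracy <- function(object) object@accuracy

#' Checkpoint display names ("Model_<acc%>")
#' @param object a CheckpointSet with measured accuracies.
#' @export
checkpointNames <- function(object) {
  vapply(object@accuracy, function(a)
    if (is.na(a)) NA_character_ else nameCheckpoint(a), character(1))
}

#' Fidelity report rows
#' @param object a FidelityReport.
#' @export
reportTable <- function(object) object@table

#' Fidelity report per-checkpoint summary
#' @param object a FidelityReport.
#' @export
reportSummary <- function(object) object@summary

#' @importFrom methods show
setMethod("show", "SmilesVocabulary", function(object) {
  cat("SmilesVocabulary with", length(object@tokens), "tokens",
      "(4 reserved)\n")
})

setMethod("show", "SmilesCorpus", function(object) {
  cat("SmilesCorpus:", nrow(object@records), "translation pairs,",
      length(unique(object@bucket)), "buckets,",
      length(object@vocabulary), "vocabulary tokens\n")
})

setMethod("show", "EDModel", function(object) {
  cfg <- object@config
  cat("EDModel: encoder", paste(cfg$encoder_units, collapse = "/"),
      "-> latent", cfg$latent_dim, "(tanh) -> decoder init",
      cfg$decoder_init_width, "\n")
})

setMethod("show", "CheckpointSet", function(object) {
  nm <- checkpointNames(object)
  cat("CheckpointSet with", length(object@epochs), "snapshots at epochs",
      paste(object@epochs, collapse = ", "), "\n")
  if (!all(is.na(nm)))
    cat("  names:", paste(nm, collapse = ", "), "\n")
})

setMethod("show", "FidelityReport", function(object) {
  cat("FidelityReport over", nrow(object@summary), "checkpoints\n")
  print(object@summary)
})
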