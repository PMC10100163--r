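# Substructure fidelity: fingerprint-level agreement between input and
# decoded molecules per checkpoint.

#' Tanimoto similarity of binary fingerprints
#'
#' Intersection over union of the on-bit sets:
#' \eqn{|a \wedge b| / (|a| + |b| - |a \wedge b|)}. When both vectors are
#' empty the similarity is defined as 1 (identical empty substructure
#' sets), with a warning.
#'
#' @param a,b binary vectors of equal length, or matrices of equal shape
#'   (row-wise similarity).
#' @return similarity in [0, 1] (vector for matrix input).
#' @export
tanimotoSimilarity <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
    inter <- rowSums(a & b)
    union <- rowSums(a != 0) + rowSums(b != 0) - inter
    if (any(union == 0)) warning("both fingerprints empty for ",
                                 sum(union == 0), " pair(s); Tanimoto = 1")
    ifelse(union == 0, 1, inter / union)
  } else {
    if (length(a) != length(b)) stop("fingerprint length mismatch")
    inter <- sum(a & b)
    union <- sum(a != 0) + sum(b != 0) - inter
    if (union == 0) {
      warning("both fingerprints empty; Tanimoto defined as 1")
      return(1)
    }
    inter / union
  }
}

#' Select molecules decoded validly by every qualifying checkpoint
#'
#' Keeps the molecules whose decoded output is a valid structure under
#' EVERY checkpoint whose measured perfect accuracy exceeds
#' `min_accuracy_threshold` (default 0.001, i.e. above "Model_0.1"; the
#' untrained model is excluded by the threshold). Restricting all
#' checkpoints to a common subset makes the per-checkpoint agreement means
#' comparable.
#'
#' @param translations list of translation data.frames (one per
#'   checkpoint, from [translateSet()], aligned on the same evaluation
#'   molecules).
#' @param accuracies measured perfect accuracy per checkpoint.
#' @param min_accuracy_threshold strict lower bound on accuracy for a
#'   checkpoint to qualify. Default 0.001.
#' @return list with `subset` (molecule indices), `qualifying` (checkpoint
#'   indices).
#' @export
selectCommonValid <- function(translations, accuracies,
                              min_accuracy_threshold = 0.001) {
  stopifnot(length(translations) == length(accuracies))
  qual <- which(accuracies > min_accuracy_threshold)
  if (!length(qual)) {
    stop("no checkpoint exceeds the accuracy threshold ",
         min_accuracy_threshold, "; lower the threshold")
  }
  n <- nrow(translations[[qual[1]]])
  keep <- rep(TRUE, n)
  for (k in qual) keep <- keep & smilesIsValid(translations[[k]]$predicted)
  if (!any(keep)) {
    stop("no molecule decodes validly under every qualifying checkpoint; ",
         "consider lowering the threshold")
  }
  list(subset = which(keep), qualifying = qual)
}

#' Fingerprint agreement between inputs and decoded structures
#'
#' For each checkpoint, computes MACCS (166-key) and ECFP (radius 2,
#' 2048-bit) fingerprints of the input molecules and their decoded
#' counterparts on a common subset, and reports mean and standard
#' deviation of the per-pair Tanimoto similarities. Agreement is judged at
#' the molecule level (strings are parsed first), so an exact string match
#' always contributes 1 to both measures.
#'
#' @param translations list of translation data.frames per checkpoint.
#' @param input_smiles canonical SMILES of the evaluation molecules (the
#'   decoding targets).
#' @param subset molecule indices from [selectCommonValid()].
#' @param checkpoint_names display names, one per checkpoint.
#' @param qualifying checkpoint indices to report (default: all).
#' @return list with `pairs` (per-pair data.frame: checkpoint, id,
#'   tanimoto_maccs, tanimoto_ecfp) and `summary` (per-checkpoint mean/sd,
#'   n retained).
#' @export
agreementByCheckpoint <- function(translations, input_smiles, subset,
                                  checkpoint_names = NULL,
                                  qualifying = seq_along(translations)) {
  if (is.null(checkpoint_names)) {
    checkpoint_names <- paste0("ckpt", seq_along(translations))
  }
  in_sub <- input_smiles[subset]
  fp_in_m <- maccsFingerprints(in_sub)
  fp_in_e <- ecfpFingerprints(in_sub)
  pairs <- list(); summ <- list()
  for (k in qualifying) {
    pred <- translations[[k]]$predicted[subset]
    fp_p_m <- maccsFingerprints(pred)
    fp_p_e <- ecfpFingerprints(pred)
    tm <- suppressWarnings(tanimotoSimilarity(fp_in_m, fp_p_m))
    te <- suppressWarnings(tanimotoSimilarity(fp_in_e, fp_p_e))
    pairs[[length(pairs) + 1L]] <- data.frame(
      checkpoint = checkpoint_names[k], id = subset,
      tanimoto_maccs = tm, tanimoto_ecfp = te)
    summ[[length(summ) + 1L]] <- data.frame(
      checkpoint = checkpoint_names[k], n = length(subset),
      maccs_mean = mean(tm), maccs_sd = sd(tm),
      ecfp_mean = mean(te), ecfp_sd = sd(te))
  }
  list(pairs = do.call(rbind, pairs), summary = do.call(rbind, summ))
}
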