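# Translation-fidelity metrics. Both metrics compare raw character
# strings: perfect accuracy is whole-string equality; partial accuracy is
# the mean per-position character agreement from the start of the strings,
# normalized by the longer string's length. Multi-character tokens are NOT
# collapsed -- comparison is per letter.

#' Perfect translation accuracy
#'
#' Fraction of pairs whose predicted SMILES equals the correct SMILES
#' exactly, character for character:
#' \deqn{\frac{1}{n}\sum_i I(t = p)}
#'
#' @param t character vector of correct SMILES.
#' @param p character vector of predicted SMILES, same length.
#' @return proportion in [0, 1].
#' @export
perfectAccuracy <- function(t, p) {
  if (length(t) != length(p)) stop("t and p must have equal length")
  if (length(t) == 0L) stop("empty evaluation batch")
  mean(t == p)
}

#' Partial translation accuracy
#'
#' Mean per-chemical positional agreement:
#' \deqn{\frac{1}{n}\sum_i \frac{1}{\max(l(t),l(p))}
#'       \sum_{j=1}^{\min(l(t),l(p))} I(t_j = p_j)}
#' Characters are compared position by position from the start. A pair of
#' two empty strings contributes 1 (identical strings); an empty string
#' against a non-empty one contributes 0.
#'
#' @inheritParams perfectAccuracy
#' @return proportion in [0, 1].
#' @export
partialAccuracy <- function(t, p) {
  if (length(t) != length(p)) stop("t and p must have equal length")
  if (length(t) == 0L) stop("empty evaluation batch")
  per <- mapply(function(ti, pi) {
    lt <- nchar(ti); lp <- nchar(pi)
    if (lt == 0L && lp == 0L) return(1)
    mx <- max(lt, lp); mn <- min(lt, lp)
    if (mn == 0L) return(0)
    tc <- strsplit(ti, "", fixed = TRUE)[[1]]
    pc <- strsplit(pi, "", fixed = TRUE)[[1]]
    sum(tc[seq_len(mn)] == pc[seq_len(mn)]) / mx
  }, t, p, USE.NAMES = FALSE)
  mean(per)
}

#' Checkpoint display name from measured perfect accuracy
#'
#' Formats "Model_<accuracy in percent>": whole percent at or above 1%
#' ("Model_94"), one decimal below 1% ("Model_0.1"), "Model_0" at zero.
#'
#' @param perfect_accuracy value in [0, 1].
#' @return display name string.
#' @export
nameCheckpoint <- function(perfect_accuracy) {
  if (!is.numeric(perfect_accuracy) || is.na(perfect_accuracy) ||
      perfect_accuracy < 0 || perfect_accuracy > 1) {
    stop("perfect_accuracy must be a number in [0, 1]")
  }
  pct <- 100 * perfect_accuracy
  lab <- if (pct >= 1) sprintf("%g", round(pct)) else sprintf("%g",
                                                             round(pct, 1))
  paste0("Model_", lab)
}

#' Evaluate a checkpoint set on replicate evaluation sets
#'
#' For every checkpoint and every evaluation set: translate the randomized
#' SMILES, score perfect accuracy, partial accuracy and the fraction of
#' decoded strings that are valid SMILES; summarize replicate means and
#' standard deviations; assign display names from mean perfect accuracy.
#' Evaluation sets must be disjoint from the training corpus (checked on
#' canonical SMILES) unless `allow_overlap` is set, as when scoring a
#' memorization fixture on its own training molecules.
#'
#' @param checkpoints a \linkS4class{CheckpointSet}.
#' @param eval_sets a list of molecule record data.frames (each with
#'   `canonical_smiles` and `random_smiles`), or one such data.frame.
#' @param train_smiles canonical SMILES of the training corpus, used for
#'   the disjointness check (optional).
#' @param allow_overlap skip the disjointness check.
#' @return list with `report` (a \linkS4class{FidelityReport}) and
#'   `checkpoints` (the checkpoint set with measured accuracies filled in).
#' @export
evaluateModelSet <- function(checkpoints, eval_sets, train_smiles = NULL,
                             allow_overlap = FALSE) {
  stopifnot(is(checkpoints, "CheckpointSet"))
  if (is.data.frame(eval_sets)) eval_sets <- list(eval_sets)
  if (!is.null(train_smiles) && !allow_overlap) {
    for (es in eval_sets) {
      ov <- intersect(es$canonical_smiles, train_smiles)
      if (length(ov)) {
        stop("evaluation set overlaps the training corpus: ",
             paste(utils::head(ov, 5L), collapse = ", "))
      }
    }
  }
  rows <- list()
  for (k in seq_along(checkpoints@epochs)) {
    mdl <- checkpoints@models[[k]]
    for (s in seq_along(eval_sets)) {
      es <- eval_sets[[s]]
      tr <- translateSet(mdl, es$random_smiles)
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = checkpoints@epochs[k], eval_set = s,
        perfect = perfectAccuracy(es$canonical_smiles, tr$predicted),
        partial = partialAccuracy(es$canonical_smiles, tr$predicted),
        validity = mean(smilesIsValid(tr$predicted)))
    }
  }
  tb <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tb, tb$epoch), function(d) {
    data.frame(epoch = d$epoch[1],
               perfect_mean = mean(d$perfect), perfect_sd = sd(d$perfect),
               partial_mean = mean(d$partial), partial_sd = sd(d$partial),
               validity_mean = mean(d$validity))
  }))
  agg <- agg[order(agg$epoch), , drop = FALSE]
  checkpoints@accuracy <- agg$perfect_mean[match(checkpoints@epochs,
                                                 agg$epoch)]
  nm <- checkpointNames(checkpoints)
  agg$checkpoint <- nm[match(agg$epoch, checkpoints@epochs)]
  tb$checkpoint <- nm[match(tb$epoch, checkpoints@epochs)]
  rownames(agg) <- rownames(tb) <- NULL
  rep <- new("FidelityReport",
             table = tb[, c("checkpoint", "epoch", "eval_set", "perfect",
                            "partial", "validity")],
             summary = agg[, c("checkpoint", "epoch", "perfect_mean",
                               "perfect_sd", "partial_mean", "partial_sd",
                               "validity_mean")])
  list(report = rep, checkpoints = checkpoints)
}

#' Write a fidelity report to CSV and JSON
#'
#' @param report a \linkS4class{FidelityReport}.
#' @param dir output directory.
#' @export
writeFidelityReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@table, file.path(dir, "fidelity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(table = report@table, summary = report@summary),
                       file.path(dir, "fidelity.json"), dataframe = "rows",
                       digits = NA)
  invisible(dir)
}
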