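# Misprediction analysis: characterize wrongly restored structures via
# string length and molecular weight of actual vs predicted SMILES.

#' Collect misprediction records for one checkpoint
#'
#' Exactly the translation pairs that fail whole-string equality. String
#' lengths are character counts; molecular weight is computed only for
#' predictions that parse as valid structures (others carry NA and
#' `pred_valid = FALSE` but stay in the length statistics).
#'
#' @param translation a data.frame from [translateSet()].
#' @param targets canonical SMILES the decoder should have produced,
#'   aligned with `translation`.
#' @param checkpoint display name recorded with each row.
#' @return data.frame: checkpoint, true_smiles, pred_smiles, l_true,
#'   l_pred, mw_true, mw_pred, pred_valid.
#' @export
collectMispredictions <- function(translation, targets,
                                  checkpoint = "checkpoint") {
  stopifnot(nrow(translation) == length(targets))
  wrong <- which(translation$predicted != targets)
  if (!length(wrong)) {
    return(data.frame(checkpoint = character(0), true_smiles = character(0),
                      pred_smiles = character(0), l_true = integer(0),
                      l_pred = integer(0), mw_true = numeric(0),
                      mw_pred = numeric(0), pred_valid = logical(0)))
  }
  ts <- targets[wrong]
  ps <- translation$predicted[wrong]
  valid <- smilesIsValid(ps)
  mw_true <- molProperties(ts)$mw
  mw_pred <- rep(NA_real_, length(ps))
  if (any(valid)) mw_pred[valid] <- molProperties(ps[valid])$mw
  data.frame(checkpoint = checkpoint, true_smiles = ts, pred_smiles = ps,
             l_true = nchar(ts), l_pred = nchar(ps),
             mw_true = mw_true, mw_pred = mw_pred, pred_valid = valid,
             stringsAsFactors = FALSE)
}

#' Summarize length and molecular-weight bias of mispredictions
#'
#' Against the y = x reference (prediction equals truth), reports how often
#' and how far the decoder overshoots: the fraction of mispredictions with
#' a longer predicted string, the mean length difference, and the same for
#' molecular weight among valid predictions.
#'
#' @param records data.frame from [collectMispredictions()] (one
#'   checkpoint).
#' @return one-row data.frame: n, frac_longer, mean_dlen, n_valid_mw,
#'   frac_heavier, mean_dmw. With no records, n = 0 and the statistics are
#'   NA.
#' @export
summarizeBias <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(n = 0L, frac_longer = NA_real_, mean_dlen = NA_real_,
                      n_valid_mw = 0L, frac_heavier = NA_real_,
                      mean_dmw = NA_real_))
  }
  dlen <- records$l_pred - records$l_true
  v <- records$pred_valid & !is.na(records$mw_pred)
  dmw <- records$mw_pred[v] - records$mw_true[v]
  data.frame(n = nrow(records),
             frac_longer = mean(dlen > 0),
             mean_dlen = mean(dlen),
             n_valid_mw = sum(v),
             frac_heavier = if (any(v)) mean(dmw > 0) else NA_real_,
             mean_dmw = if (any(v)) mean(dmw) else NA_real_)
}

#' Scatter plot of misprediction bias against the y = x line
#'
#' @param records data.frame from [collectMispredictions()].
#' @param what "length" (string lengths) or "mw" (molecular weights of
#'   valid predictions).
#' @return a ggplot object.
#' @export
plotMisprediction <- function(records, what = c("length", "mw")) {
  what <- match.arg(what)
  if (what == "length") {
    d <- data.frame(x = records$l_true, y = records$l_pred)
    labs <- c("actual SMILES length", "predicted SMILES length")
  } else {
    keep <- records$pred_valid & !is.na(records$mw_pred)
    d <- data.frame(x = records$mw_true[keep], y = records$mw_pred[keep])
    labs <- c("actual molecular weight (Da)",
              "predicted molecular weight (Da)")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "orange") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_bw()
}
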