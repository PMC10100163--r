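# Latent-representation probing: downstream classification from the
# bottleneck descriptors (gradient-boosted trees, AUROC/MCC) and
# chemical-space embedding with similarity-group highlighting.

#' Matthews correlation coefficient from a confusion table
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return MCC in [-1, 1]; 0 when a marginal is empty.
#' @export
matthewsCorrelation <- function(tp, tn, fp, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  num / den
}

# bounded random hyperparameter search space for the boosted-tree probe
.probeTrialParams <- function(n_trials) {
  data.frame(
    eta = exp(runif(n_trials, log(0.03), log(0.3))),
    max_depth = sample(2:6, n_trials, replace = TRUE),
    subsample = runif(n_trials, 0.6, 1),
    colsample_bytree = runif(n_trials, 0.6, 1),
    min_child_weight = sample(c(1, 3, 5), n_trials, replace = TRUE),
    nrounds = sample(c(50L, 100L, 150L, 200L), n_trials, replace = TRUE))
}

#' Probe a descriptor matrix with a gradient-boosted classifier
#'
#' Holds out 25% of the rows as a test set, tunes a gradient-boosted
#' decision-tree classifier by bounded random search under 3-fold
#' cross-validated AUROC on the remainder, refits the best configuration,
#' and scores once on the held-out test set: AUROC from the predicted
#' scores, MCC from predictions thresholded at 0.5. Fully seeded.
#'
#' @param descriptors numeric matrix, one row per molecule.
#' @param labels 0/1 vector aligned with the rows; both classes required.
#' @param test_idx optional fixed test-set indices (used to keep splits
#'   identical across checkpoints); when NULL a seeded 25% split is drawn.
#' @param n_trials hyperparameter search budget. Default 20.
#' @param seed integer seed.
#' @return list: auroc, mcc, test_idx, best (chosen hyperparameters).
#' @export
runProbe <- function(descriptors, labels, test_idx = NULL, n_trials = 20L,
                     seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(nrow(descriptors) == length(labels))
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(labels)
  if (is.null(test_idx)) test_idx <- sort(sample.int(n, round(0.25 * n)))
  tr_idx <- setdiff(seq_len(n), test_idx)
  xtr <- descriptors[tr_idx, , drop = FALSE]; ytr <- labels[tr_idx]
  xte <- descriptors[test_idx, , drop = FALSE]; yte <- labels[test_idx]
  if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L) {
    stop("train or test split lost a class; use a larger sample")
  }
  folds <- split(sample(seq_along(ytr)),
                 rep_len(1:3, length(ytr)))
  trials <- .probeTrialParams(n_trials)
  cv_auc <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    pars <- list(objective = "binary:logistic", eval_metric = "auc",
                 eta = trials$eta[i], max_depth = trials$max_depth[i],
                 subsample = trials$subsample[i],
                 colsample_bytree = trials$colsample_bytree[i],
                 min_child_weight = trials$min_child_weight[i],
                 nthread = 1)
    aucs <- vapply(folds, function(va) {
      dtr <- xgboost::xgb.DMatrix(xtr[-va, , drop = FALSE],
                                  label = ytr[-va])
      fit <- xgboost::xgb.train(pars, dtr, nrounds = trials$nrounds[i],
                                verbose = 0)
      pr <- predict(fit, xgboost::xgb.DMatrix(xtr[va, , drop = FALSE]))
      if (length(unique(ytr[va])) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(ytr[va], pr, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, numeric(1))
    cv_auc[i] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)
  pars <- list(objective = "binary:logistic",
               eta = trials$eta[best], max_depth = trials$max_depth[best],
               subsample = trials$subsample[best],
               colsample_bytree = trials$colsample_bytree[best],
               min_child_weight = trials$min_child_weight[best],
               nthread = 1)
  set.seed(seed + 1L)
  fit <- xgboost::xgb.train(pars, xgboost::xgb.DMatrix(xtr, label = ytr),
                            nrounds = trials$nrounds[best], verbose = 0)
  pr <- predict(fit, xgboost::xgb.DMatrix(xte))
  auroc <- as.numeric(pROC::auc(pROC::roc(yte, pr, quiet = TRUE,
                                          direction = "<",
                                          levels = c(0, 1))))
  cls <- as.integer(pr >= 0.5)
  mcc <- matthewsCorrelation(sum(cls == 1 & yte == 1),
                             sum(cls == 0 & yte == 0),
                             sum(cls == 1 & yte == 0),
                             sum(cls == 0 & yte == 1))
  list(auroc = auroc, mcc = mcc, test_idx = test_idx,
       best = trials[best, , drop = FALSE])
}

#' Probe every checkpoint's descriptors on one task
#'
#' Extracts latent descriptors per checkpoint and runs [runProbe()] with an
#' identical train/test split and search budget for every checkpoint, so
#' the AUROC/MCC values are comparable across training progress.
#'
#' @param checkpoints a \linkS4class{CheckpointSet}.
#' @param smiles molecule SMILES fed to the encoders.
#' @param labels 0/1 task labels aligned with `smiles`.
#' @param n_trials search budget per checkpoint. Default 20.
#' @param seed integer seed (split and search).
#' @return data.frame ordered by epoch: checkpoint, epoch, auroc, mcc.
#' @export
probeModelSet <- function(checkpoints, smiles, labels, n_trials = 20L,
                          seed = 1L) {
  stopifnot(is(checkpoints, "CheckpointSet"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(smiles)
  test_idx <- sort(sample.int(n, round(0.25 * n)))
  nm <- checkpointNames(checkpoints)
  res <- lapply(seq_along(checkpoints@epochs), function(k) {
    z <- encodeMolecules(checkpoints@models[[k]], smiles)
    pr <- runProbe(z, labels, test_idx = test_idx, n_trials = n_trials,
                   seed = seed)
    data.frame(checkpoint = nm[k], epoch = checkpoints@epochs[k],
               auroc = pr$auroc, mcc = pr$mcc, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Assign molecules to reference-compound similarity groups
#'
#' A molecule joins a group when the ECFP Tanimoto similarity with the
#' group's reference compound is strictly greater than the threshold
#' (default 0.25) and the molecule is not on the group's exclusion list. A
#' molecule may join several groups.
#'
#' @param smiles character vector of molecule SMILES.
#' @param groups list of groups, each a list with `name`, `reference`
#'   (SMILES), optional `threshold` (default 0.25) and optional `exclude`
#'   (character vector of SMILES or ids).
#' @param ids optional identifiers matched against exclusion lists
#'   (defaults to the SMILES themselves).
#' @return logical membership matrix, one row per molecule, one column per
#'   group.
#' @export
assignSimilarityGroups <- function(smiles, groups, ids = smiles) {
  stopifnot(length(ids) == length(smiles))
  refs <- vapply(groups, `[[`, character(1), "reference")
  if (!all(smilesIsValid(refs))) {
    stop("unparseable reference SMILES in group definition")
  }
  fp <- ecfpFingerprints(smiles)
  fr <- ecfpFingerprints(refs)
  memb <- matrix(FALSE, length(smiles), length(groups),
                 dimnames = list(NULL, vapply(groups, `[[`, character(1),
                                              "name")))
  for (gidx in seq_along(groups)) {
    g <- groups[[gidx]]
    thr <- if (is.null(g$threshold)) 0.25 else g$threshold
    sim <- tanimotoSimilarity(fp, matrix(fr[gidx, ], nrow(fp), ncol(fr),
                                         byrow = TRUE))
    inside <- sim > thr
    if (!is.null(g$exclude)) inside <- inside & !(ids %in% g$exclude)
    memb[, gidx] <- inside
  }
  memb
}

#' Embed descriptors into a 2-D chemical-space map
#'
#' UMAP embedding of the latent descriptors with a fixed seed, returning a
#' plotting-ready table with similarity-group flags.
#'
#' @param descriptors numeric matrix with at least 10 rows.
#' @param membership optional logical matrix from
#'   [assignSimilarityGroups()].
#' @param seed integer seed; the same seed reproduces identical
#'   coordinates.
#' @param n_neighbors UMAP neighborhood size. Default 15 (capped at
#'   n - 1).
#' @param ids row identifiers for the output table.
#' @return data.frame: id, x, y, plus one logical column per group.
#' @export
embedChemicalSpace <- function(descriptors, membership = NULL, seed = 1L,
                               n_neighbors = 15L,
                               ids = seq_len(nrow(descriptors))) {
  if (nrow(descriptors) < 10L) stop("need at least 10 molecules to embed")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  emb <- uwot::umap(descriptors,
                    n_neighbors = min(n_neighbors, nrow(descriptors) - 1L),
                    n_threads = 1, n_sgd_threads = 0)
  out <- data.frame(id = ids, x = emb[, 1], y = emb[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(membership)) out <- cbind(out, as.data.frame(membership))
  out
}

#' Chemical-space scatter plot with group highlighting
#'
#' @param embedding data.frame from [embedChemicalSpace()].
#' @param group_cols names of logical group columns to highlight (default:
#'   all non-coordinate columns).
#' @return a ggplot object.
#' @export
plotChemicalSpace <- function(embedding,
                              group_cols = setdiff(names(embedding),
                                                   c("id", "x", "y"))) {
  grp <- rep("other", nrow(embedding))
  for (g in group_cols) grp[embedding[[g]]] <- g
  d <- data.frame(x = embedding$x, y = embedding$y,
                  group = factor(grp, levels = c("other", group_cols)))
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y, colour = group)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c("grey70", scales_hue(length(group_cols)))) +
    ggplot2::theme_bw()
}

# small fixed palette without pulling in scales
scales_hue <- function(n) {
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                 c = 100, l = 55)
}
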