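# Synthetic corpus generator: valid, diverse organic molecules assembled
# from a fixed scaffold library plus a substituent library, validated by
# the chemistry toolkit. Stands in for an external compound library so the
# full analysis runs at desk scale.

# Scaffolds as token templates. `sites` are token positions after which a
# "(substituent)" branch may be inserted (the position covers the atom and
# its ring-opening digit); `stereo_sites` are ring-carbon positions that
# can host a chirality tag.
.SCAFFOLDS <- list(
  benzene      = list(tokens = c("c","1","c","c","c","c","c","1"),
                      sites = c(2L,3L,4L,5L,6L), stereo_sites = integer(0)),
  pyridine     = list(tokens = c("c","1","c","c","n","c","c","1"),
                      sites = c(2L,3L,4L,6L), stereo_sites = integer(0)),
  furan        = list(tokens = c("c","1","c","c","o","c","1"),
                      sites = c(2L,3L,4L), stereo_sites = integer(0)),
  cyclohexane  = list(tokens = c("C","1","C","C","C","C","C","1"),
                      sites = c(2L,3L,4L,5L,6L), stereo_sites = c(3L,4L,5L,6L)),
  cyclopentane = list(tokens = c("C","1","C","C","C","C","1"),
                      sites = c(2L,3L,4L,5L), stereo_sites = c(3L,4L,5L)),
  propane      = list(tokens = c("C","C","C"),
                      sites = c(1L,2L,3L), stereo_sites = integer(0)),
  butane       = list(tokens = c("C","C","C","C"),
                      sites = c(1L,2L,3L,4L), stereo_sites = integer(0)),
  isobutane    = list(tokens = c("C","C","(","C",")","C"),
                      sites = c(1L,2L,4L,6L), stereo_sites = integer(0)),
  pentane      = list(tokens = c("C","C","C","C","C"),
                      sites = c(1L,2L,3L,4L,5L), stereo_sites = integer(0)))

# Substituent library with sampling weights. Hydroxyl-bearing groups are
# weighted so that a hydroxyl-type label rule covers roughly 20-50% of the
# default corpus, keeping the downstream probe task balanced.
.SUBSTITUENTS <- data.frame(
  name   = c("methyl","hydroxyl","amino","fluoro","chloro","bromo",
             "carboxyl","nitrile","methoxy","ethyl","propyl","butyl"),
  smiles = c("C","O","N","F","Cl","Br","C(=O)O","C#N","OC","CC","CCC","CCCC"),
  weight = c(1.0, 1.5, 1.0, 0.7, 0.7, 0.4, 0.8, 0.6, 0.8, 0.8, 0.5, 0.3),
  stringsAsFactors = FALSE)

.N_SUB_PROBS <- c(0.15, 0.30, 0.25, 0.20, 0.10)  # 0..4 substituents

#' Configuration for the synthetic molecule generator
#'
#' @param n_molecules number of unique molecules to generate.
#' @param heavy_atom_range inclusive heavy-atom bounds; lower bound >= 3.
#' @param stereo_fraction proportion of molecules given at least one
#'   confirmed stereocenter. Default 0.1.
#' @param scaffold_set names of built-in scaffolds to draw from.
#' @param substituent_set names of built-in substituents to draw from.
#' @param seed integer; the same seed and configuration reproduce the
#'   output byte for byte.
#' @return validated configuration list.
#' @export
generatorConfig <- function(n_molecules, heavy_atom_range = c(3L, 50L),
                            stereo_fraction = 0.1,
                            scaffold_set = names(.SCAFFOLDS),
                            substituent_set = .SUBSTITUENTS$name,
                            seed = 1L) {
  stopifnot(n_molecules >= 1L,
            length(heavy_atom_range) == 2L,
            heavy_atom_range[1] >= 3L,
            heavy_atom_range[1] <= heavy_atom_range[2],
            stereo_fraction >= 0, stereo_fraction <= 1,
            all(scaffold_set %in% names(.SCAFFOLDS)),
            all(substituent_set %in% .SUBSTITUENTS$name))
  list(n_molecules = as.integer(n_molecules),
       heavy_atom_range = as.integer(heavy_atom_range),
       stereo_fraction = stereo_fraction,
       scaffold_set = scaffold_set,
       substituent_set = substituent_set,
       seed = as.integer(seed))
}

# Assemble one candidate SMILES string (possibly with a chirality tag).
.assembleCandidate <- function(scaffolds, subs, want_stereo) {
  if (want_stereo) {
    ok <- vapply(scaffolds, function(s) length(s$stereo_sites) > 0L, logical(1))
    scaffolds <- scaffolds[ok]
  }
  sc <- scaffolds[[sample.int(length(scaffolds), 1L)]]
  toks <- sc$tokens
  sites <- sc$sites
  k <- sample.int(5L, 1L, prob = .N_SUB_PROBS) - 1L
  ins <- list()
  if (want_stereo) {
    st <- sc$stereo_sites[sample.int(length(sc$stereo_sites), 1L)]
    tag <- if (runif(1) < 0.5) "[C@H]" else "[C@@H]"
    toks[st] <- tag
    si <- sample.int(nrow(subs), 1L, prob = subs$weight)
    ins[[length(ins) + 1L]] <- list(pos = st, smi = subs$smiles[si])
    sites <- setdiff(sites, st)
    k <- max(k, 1L)  # at least one more substituent to break ring symmetry
  }
  k <- min(k, length(sites))
  if (k > 0L) {
    at <- sample(sites, k)
    si <- sample.int(nrow(subs), k, replace = TRUE, prob = subs$weight)
    for (j in seq_len(k)) {
      ins[[length(ins) + 1L]] <- list(pos = at[j], smi = subs$smiles[si[j]])
    }
  }
  if (length(ins)) {
    ord <- order(vapply(ins, `[[`, 1L, "pos"), decreasing = TRUE)
    for (j in ord) {
      p <- ins[[j]]$pos
      branch <- c("(", tokenizeSmiles(ins[[j]]$smi), ")")
      toks <- append(toks, branch, after = p)
    }
  }
  paste(toks, collapse = "")
}

#' Generate synthetic molecules
#'
#' Builds `n_molecules` unique, valid organic molecules by attaching 0-4
#' substituents from a fixed library to a fixed scaffold library, with
#' optional ring stereocenters (a chirality-tagged ring carbon carrying a
#' substituent, retried until the toolkit's canonical form confirms the
#' stereocenter). Every record passes the corpus admission filter by
#' construction: organic elements only, single fragment, heavy atoms within
#' range, unique canonical SMILES.
#'
#' @param config a [generatorConfig()].
#' @return molecule record data.frame: id, canonical_smiles, random_smiles,
#'   n_heavy, mw, has_stereo.
#' @export
generateMolecules <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  scaffolds <- .SCAFFOLDS[config$scaffold_set]
  subs <- .SUBSTITUENTS[.SUBSTITUENTS$name %in% config$substituent_set, ]
  n <- config$n_molecules
  # fixed quotas keep the stereo fraction on target: rejection sampling
  # alone would over-represent stereo molecules (their combinatorial
  # space deduplicates less often)
  n_stereo <- as.integer(round(n * config$stereo_fraction))
  n_plain <- n - n_stereo
  budget <- 50L * n
  attempts <- 0L
  seen <- character(0)
  got <- c(plain = 0L, stereo = 0L)
  recs <- list()

  while ((got["plain"] < n_plain || got["stereo"] < n_stereo) &&
         attempts < budget) {
    chunk <- min(max(64L, 2L * (n - length(seen))), budget - attempts)
    attempts <- attempts + chunk
    p_st <- if (got["plain"] >= n_plain) 1 else
            if (got["stereo"] >= n_stereo) 0 else config$stereo_fraction
    want_stereo <- runif(chunk) < p_st
    cand <- vapply(want_stereo, function(w)
      .assembleCandidate(scaffolds, subs, w), character(1))
    ok <- smilesIsValid(cand)
    cand <- cand[ok]; want_stereo <- want_stereo[ok]
    if (!length(cand)) next
    can <- canonicalizeSmiles(cand)
    pr <- molProperties(cand)
    keep <- pr$n_heavy >= config$heavy_atom_range[1] &
            pr$n_heavy <= config$heavy_atom_range[2] &
            (pr$has_stereo | !want_stereo) &   # stereo request must stick
            !duplicated(can) & !(can %in% seen)
    # honor the per-category quotas in order
    for (i in which(keep)) {
      cat_i <- if (pr$has_stereo[i]) "stereo" else "plain"
      lim <- if (cat_i == "stereo") n_stereo else n_plain
      if (got[cat_i] >= lim) { keep[i] <- FALSE; next }
      got[cat_i] <- got[cat_i] + 1L
    }
    if (!any(keep)) next
    seen <- c(seen, can[keep])
    recs[[length(recs) + 1L]] <- data.frame(
      canonical_smiles = can[keep], n_heavy = pr$n_heavy[keep],
      mw = pr$mw[keep], has_stereo = pr$has_stereo[keep],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  if (is.null(rec) || nrow(rec) < n) {
    stop("could not assemble ", n, " unique valid molecules within the ",
         "attempt budget (", budget, " attempts); generated ",
         if (is.null(rec)) 0L else nrow(rec))
  }
  rec <- rec[seq_len(n), , drop = FALSE]
  rec$id <- paste0("M", seq_len(n))
  rec$random_smiles <- enumerateRandomSmiles(rec$canonical_smiles,
                                             seed = config$seed + 1L)
  rownames(rec) <- NULL
  rec[, c("id", "canonical_smiles", "random_smiles", "n_heavy", "mw",
          "has_stereo")]
}

#' Configuration for rule-based synthetic labels
#'
#' @param rule_substructure SMARTS pattern defining activity (default
#'   hydroxyl, `"[OX2H]"`).
#' @param noise_rate proportion of labels flipped, in [0, 0.5).
#' @param positive_fraction_target intended positive fraction, in (0, 1);
#'   used for the balance warning.
#' @param seed integer seed for the noise draws.
#' @export
labelConfig <- function(rule_substructure = "[OX2H]", noise_rate = 0.1,
                        positive_fraction_target = 0.3, seed = 1L) {
  stopifnot(is.character(rule_substructure), nzchar(rule_substructure),
            noise_rate >= 0, noise_rate < 0.5,
            positive_fraction_target > 0, positive_fraction_target < 1)
  list(rule_substructure = rule_substructure, noise_rate = noise_rate,
       positive_fraction_target = positive_fraction_target,
       seed = as.integer(seed))
}

#' Generate rule-based binary activity labels
#'
#' Each molecule's label is (matches the rule substructure) XOR (a flip
#' drawn with probability `noise_rate`), emulating a noisy assay readout
#' driven by one substructure. A warning is issued when the noiseless
#' positive fraction falls below 5% (an unbalanced, hardly learnable task)
#' or the rule matches nothing.
#'
#' @param molecules molecule record data.frame or character vector of
#'   SMILES.
#' @param config a [labelConfig()].
#' @return integer 0/1 vector with attributes `positive_fraction` (after
#'   noise) and `base_positive_fraction` (noiseless).
#' @export
generateLabels <- function(molecules, config) {
  smiles <- if (is.data.frame(molecules)) molecules$canonical_smiles
            else molecules
  if (length(smiles) == 0L) stop("empty molecule list")
  base <- as.integer(smartsMatches(smiles, config$rule_substructure) > 0L)
  pf <- mean(base)
  if (pf == 0) {
    warning("label rule '", config$rule_substructure,
            "' matches no molecule; all base labels are 0")
  } else if (pf < 0.05) {
    warning("noiseless positive fraction ", sprintf("%.3f", pf),
            " is below 0.05; the probe task may be unlearnable")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  flip <- as.integer(runif(length(base)) < config$noise_rate)
  labels <- bitwXor(base, flip)
  attr(labels, "base_positive_fraction") <- pf
  attr(labels, "positive_fraction") <- mean(labels)
  labels
}

#' Write molecules and labels as a CSV label table
#'
#' @param molecules molecule record data.frame.
#' @param labels 0/1 vector from [generateLabels()].
#' @param path output CSV path (columns: id, smiles, label).
#' @export
writeLabels <- function(molecules, labels, path) {
  stopifnot(nrow(molecules) == length(labels))
  utils::write.csv(
    data.frame(id = molecules$id, smiles = molecules$canonical_smiles,
               label = as.integer(labels)),
    path, row.names = FALSE)
  invisible(path)
}
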