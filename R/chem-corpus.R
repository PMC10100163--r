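# Corpus preparation: filtering, salt stripping, canonicalization,
# randomized-SMILES enumeration, tokenization, vocabulary and
# length/stereo bucketing.

.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\[\\]]*\\]",          # bracket atoms, single token
  "|Br|Cl",                    # two-character organic-subset atoms
  "|%[0-9]{2}",                # two-digit ring-bond labels
  "|[BCNOPSFIbcnops]",         # one-character atoms
  "|[0-9]",                    # ring-bond digits
  "|[()=#/\\\\.+@~*-]")        # bonds, branches, dots

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into model tokens. Multi-character atoms ("Cl",
#' "Br"), bracket atoms ("[C@@H]", "[nH]") and two-digit ring labels
#' ("%12") are single tokens; everything else is one character per token.
#' `detokenizeSmiles(tokenizeSmiles(s))` is the identity for any valid
#' SMILES.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
tokenizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  toks <- if (m[1] == -1L) character(0) else regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    stop("cannot tokenize SMILES (dangling bracket or foreign character): ",
         smiles)
  }
  toks
}

#' @rdname tokenizeSmiles
#' @param tokens character vector of tokens.
#' @export
detokenizeSmiles <- function(tokens) paste(tokens, collapse = "")

#' Build a token vocabulary from tokenized sequences
#'
#' @param token_lists list of character token vectors.
#' @return a \linkS4class{SmilesVocabulary} with the four reserved symbols
#'   (`<pad>`, `<s>`, `</s>`, `<unk>`) followed by the observed tokens in
#'   sorted order.
#' @export
buildVocabulary <- function(token_lists) {
  # radix sort = byte order, independent of the session's collation locale
  obs <- sort(unique(unlist(token_lists, use.names = FALSE)),
              method = "radix")
  obs <- setdiff(obs, .RESERVED_TOKENS)
  new("SmilesVocabulary", tokens = c(.RESERVED_TOKENS, obs))
}

#' Encode tokens to vocabulary indices / decode indices back to tokens
#'
#' @param vocab a \linkS4class{SmilesVocabulary}.
#' @param tokens character vector of tokens.
#' @param strict if TRUE (default) an out-of-vocabulary token is an error
#'   naming the token; otherwise it maps to the `<unk>` index.
#' @return integer indices (`encodeTokens`) or tokens (`decodeTokens`).
#' @export
encodeTokens <- function(vocab, tokens, strict = TRUE) {
  idx <- match(tokens, vocab@tokens)
  if (anyNA(idx)) {
    if (strict) stop("out-of-vocabulary token: ",
                     paste(unique(tokens[is.na(idx)]), collapse = ", "))
    idx[is.na(idx)] <- 4L
  }
  idx
}

#' @rdname encodeTokens
#' @param ids integer vector of vocabulary indices.
#' @export
decodeTokens <- function(vocab, ids) {
  stopifnot(all(ids >= 1L), all(ids <= length(vocab@tokens)))
  vocab@tokens[ids]
}

# Split a SMILES into top-level fragments ("." is never legal inside a
# bracket atom, so a plain split is exact).
.splitFragments <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

#' Filter and standardize raw SMILES input
#'
#' Corpus admission filter. For each input string, in order: parse; strip
#' salts by keeping the fragment with the most heavy atoms (ties broken by
#' higher molecular weight, then lexicographically smaller canonical
#' SMILES); require the organic element set
#' (H, B, C, N, O, F, P, S, Cl, Br, I); require the heavy-atom count to lie
#' in `heavy_range` (inclusive). Rejections are logged with a reason code,
#' never raised.
#'
#' @param smiles character vector of raw SMILES (possibly invalid).
#' @param ids optional identifiers (default "M1", "M2", ...).
#' @param heavy_range inclusive heavy-atom bounds, default c(3, 50).
#' @return list with `kept` (molecule record data.frame: id,
#'   canonical_smiles, n_heavy, mw, has_stereo) and `rejected` (data.frame:
#'   id, smiles, reason in unparseable | inorganic | too_small | too_large).
#' @export
filterChemicals <- function(smiles, ids = NULL, heavy_range = c(3L, 50L)) {
  stopifnot(length(heavy_range) == 2L, heavy_range[1] <= heavy_range[2])
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("M", seq_len(n))
  stopifnot(length(ids) == n)
  reason <- rep(NA_character_, n)
  keep_smiles <- rep(NA_character_, n)

  parsed <- smilesIsValid(smiles)
  reason[!parsed] <- "unparseable"

  # salt stripping: largest fragment by heavy atoms, then MW, then
  # canonical string
  for (i in which(parsed)) {
    frags <- .splitFragments(smiles[i])
    if (length(frags) == 1L) { keep_smiles[i] <- smiles[i]; next }
    ok <- smilesIsValid(frags)
    frags <- frags[ok]
    if (!length(frags)) { reason[i] <- "unparseable"; next }
    can <- canonicalizeSmiles(frags)
    pr <- molProperties(frags)
    ord <- order(-pr$n_heavy, -pr$mw, can, method = "radix")
    keep_smiles[i] <- frags[ord[1]]
  }

  idx <- which(is.na(reason))
  if (length(idx)) {
    pr <- molProperties(keep_smiles[idx])
    can <- canonicalizeSmiles(keep_smiles[idx])
    organic <- vapply(keep_smiles[idx], function(s)
      all(.smilesElements(s) %in% .ORGANIC_ELEMENTS), logical(1),
      USE.NAMES = FALSE)
    reason[idx[!organic]] <- "inorganic"
    small <- organic & pr$n_heavy < heavy_range[1]
    large <- organic & pr$n_heavy > heavy_range[2]
    reason[idx[small]] <- "too_small"
    reason[idx[large]] <- "too_large"
    keep <- organic & !small & !large
    kept <- data.frame(
      id = ids[idx[keep]],
      canonical_smiles = can[keep],
      n_heavy = pr$n_heavy[keep],
      mw = pr$mw[keep],
      has_stereo = pr$has_stereo[keep],
      stringsAsFactors = FALSE)
  } else {
    kept <- data.frame(id = character(0), canonical_smiles = character(0),
                       n_heavy = integer(0), mw = numeric(0),
                       has_stereo = logical(0))
  }
  rejected <- data.frame(id = ids[!is.na(reason)],
                         smiles = smiles[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}

#' Assign translation pairs to length/stereo buckets
#'
#' Pairs are grouped by target token length against strictly increasing
#' `boundaries` (a target of length L falls in the first bucket whose
#' boundary is >= L), and each length bucket is split into a stereo and a
#' non-stereo sub-bucket depending on whether the target carries a stereo
#' token (any token containing "@"). Sequences longer than the largest
#' boundary go to an overflow bucket with a warning.
#'
#' @param target_tokens list of target token vectors.
#' @param boundaries strictly increasing integer length thresholds.
#' @return list with `bucket` (integer ids) and `labels` (id -> readable
#'   label).
#' @export
bucketPairs <- function(target_tokens, boundaries) {
  stopifnot(length(boundaries) >= 1L, !is.unsorted(boundaries, strictly = TRUE))
  lens <- vapply(target_tokens, length, integer(1))
  stereo <- vapply(target_tokens, function(tk) any(grepl("@", tk, fixed = TRUE)),
                   logical(1))
  len_bucket <- findInterval(lens, boundaries + 1L) + 1L  # 1..K, K+1 overflow
  K <- length(boundaries)
  if (any(len_bucket > K)) {
    warning(sum(len_bucket > K), " pair(s) exceed the largest boundary (",
            boundaries[K], " tokens); assigned to the overflow bucket")
  }
  bucket <- (len_bucket - 1L) * 2L + ifelse(stereo, 2L, 1L)
  ub <- sort(unique(bucket))
  lab <- vapply(ub, function(b) {
    lb <- (b - 1L) %/% 2L + 1L
    up <- if (lb > K) "inf" else as.character(boundaries[lb])
    lo <- if (lb == 1L) 1L else boundaries[lb - 1L] + 1L
    paste0("len", lo, "-", up, if (b %% 2L == 0L) "/stereo" else "")
  }, character(1))
  names(lab) <- as.character(ub)
  list(bucket = bucket, labels = lab)
}

#' Prepare a translation corpus
#'
#' Takes a molecule record table (e.g. from [filterChemicals()] or
#' [generateMolecules()]), generates one fixed randomized-SMILES variant
#' per molecule (unless the table already carries one and `resample` is
#' FALSE), tokenizes both sides, builds the vocabulary, and assigns
#' length/stereo buckets.
#'
#' @param records molecule record data.frame with at least
#'   `canonical_smiles` (and optionally `random_smiles`).
#' @param boundaries bucket length thresholds (target tokens). Default
#'   c(10, 20, 40, 80).
#' @param seed integer seed for the enumeration.
#' @param resample if TRUE, regenerate the randomized variant even when one
#'   is present.
#' @return a \linkS4class{SmilesCorpus}.
#' @export
prepareCorpus <- function(records, boundaries = c(10L, 20L, 40L, 80L),
                          seed = 1L, resample = FALSE) {
  stopifnot(nrow(records) > 0L)
  if (is.null(records$random_smiles) || resample) {
    records$random_smiles <-
      enumerateRandomSmiles(records$canonical_smiles, seed = seed)
  }
  if (is.null(records$id)) records$id <- paste0("M", seq_len(nrow(records)))
  src_tok <- lapply(records$random_smiles, tokenizeSmiles)
  tgt_tok <- lapply(records$canonical_smiles, tokenizeSmiles)
  vocab <- buildVocabulary(c(src_tok, tgt_tok))
  bk <- bucketPairs(tgt_tok, boundaries)
  new("SmilesCorpus",
      records = records,
      source_ids = lapply(src_tok, function(tk) encodeTokens(vocab, tk)),
      target_ids = lapply(tgt_tok, function(tk) encodeTokens(vocab, tk)),
      bucket = bk$bucket, bucket_labels = bk$labels, vocabulary = vocab)
}

# ---- file formats ----------------------------------------------------------

#' Read / write SMILES line files (.smi)
#'
#' One record per line, SMILES first, optional tab-separated identifier.
#'
#' @param path file path.
#' @return `readSmi`: data.frame with columns `smiles`, `id`.
#' @export
readSmi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("M", i),
      character(1)),
    stringsAsFactors = FALSE)
}

#' @rdname readSmi
#' @param smiles character vector of SMILES.
#' @param ids identifiers, recycled/defaulted as needed.
#' @export
writeSmi <- function(smiles, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  writeLines(paste(smiles, ids, sep = "\t"), path)
  invisible(path)
}

#' Write a prepared corpus and its vocabulary to disk
#'
#' The corpus table goes to `<dir>/corpus.csv` (id, canonical_smiles,
#' random_smiles, n_heavy, mw, bucket) and the vocabulary to
#' `<dir>/vocabulary.json`.
#'
#' @param corpus a \linkS4class{SmilesCorpus}.
#' @param dir output directory (created if missing).
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- corpus@records
  out <- data.frame(id = rec$id, canonical_smiles = rec$canonical_smiles,
                    random_smiles = rec$random_smiles,
                    n_heavy = rec$n_heavy, mw = rec$mw,
                    bucket = corpus@bucket_labels[as.character(corpus@bucket)],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(dir, "corpus.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(corpus@vocabulary@tokens),
                       file.path(dir, "vocabulary.json"), auto_unbox = TRUE)
  invisible(dir)
}
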