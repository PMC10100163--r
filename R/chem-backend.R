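# Thin vectorized layer over the OpenBabel toolkit (ChemmineOB in-process,
# obabel CLI where an output option is needed). Everything downstream talks
# SMILES character vectors to these functions.

.OB_EMPTY_OPTS <- data.frame(names = character(0), args = character(0),
                             stringsAsFactors = FALSE)

# Batch SMI -> CAN conversion with title-based realignment. Returns a
# character vector aligned with `smiles`; NA where OpenBabel produced
# nothing for that input.
.obCanonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  ids <- sprintf("t%07d", seq_len(n))
  src <- paste0(paste(smiles, ids), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"),
                              options = .OB_EMPTY_OPTS),
    error = function(e) "")
  res <- rep(NA_character_, n)
  if (!nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2L && nzchar(p[[1]])) {
      idx <- match(trimws(p[[2]]), ids)
      if (!is.na(idx)) res[idx] <- p[[1]]
    }
  }
  res
}

# Structural well-formedness of a SMILES string: tokenizable, balanced
# parentheses (never negative, no empty branch), every ring-bond digit
# closed. OpenBabel alone is too lenient (it silently repairs strings such
# as "C((") to count as a validity judge for decoder output.
.smilesWellFormed <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    toks <- tryCatch(tokenizeSmiles(s), error = function(e) NULL)
    if (is.null(toks)) return(FALSE)
    depth <- 0L
    open_rings <- character(0)
    prev <- ""
    for (tk in toks) {
      if (tk == "(") {
        depth <- depth + 1L
        if (prev == "(") return(FALSE)
      } else if (tk == ")") {
        depth <- depth - 1L
        if (depth < 0L || prev == "(") return(FALSE)
      } else if (grepl("^[0-9]$|^%[0-9]{2}$", tk)) {
        key <- sub("^%", "", tk)
        if (key %in% open_rings) {
          open_rings <- setdiff(open_rings, key)
        } else {
          open_rings <- c(open_rings, key)
        }
      }
      prev <- tk
    }
    depth == 0L && length(open_rings) == 0L
  }, logical(1), USE.NAMES = FALSE)
}

#' Validity of decoded SMILES strings
#'
#' A string counts as a valid structure when it is well formed as SMILES
#' (tokenizable, balanced branches and ring bonds) and parses to a molecule
#' in the chemistry toolkit. Decoder output is judged with this predicate;
#' invalid strings are excluded from molecule-level statistics.
#'
#' @param smiles character vector of candidate SMILES strings.
#' @return logical vector.
#' @export
smilesIsValid <- function(smiles) {
  ok <- .smilesWellFormed(smiles)
  if (any(ok)) {
    can <- .obCanonical(smiles[ok])
    ok[ok] <- !is.na(can) & nzchar(can)
  }
  ok
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit's canonical form. Canonicalization is
#' idempotent and preserves stereo descriptors; string equality of two
#' canonical SMILES then means molecule identity.
#'
#' @param smiles character vector; every element must parse.
#' @return character vector of canonical SMILES, same length and order.
#' @export
canonicalizeSmiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  if (!all(.smilesWellFormed(smiles))) {
    bad <- smiles[!.smilesWellFormed(smiles)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  can <- .obCanonical(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[is.na(can)], 5L), collapse = ", "))
  }
  can
}

# Build an in-process OpenBabel molecule list for property/fingerprint
# queries. Inputs are assumed valid.
.obMols <- function(smiles) {
  src <- paste0(paste(smiles, sprintf("t%07d", seq_along(smiles))),
                collapse = "\n")
  ChemmineOB::forEachMol("SMILES", paste0(src, "\n"), identity)
}

#' Molecular properties used by the corpus filter and analyses
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with columns `mw` (average molecular weight, Da,
#'   implicit hydrogens included), `n_heavy` (heavy-atom count) and
#'   `has_stereo` (whether the canonical form carries a stereo marker).
#' @export
molProperties <- function(smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(mw = numeric(0), n_heavy = integer(0),
                      has_stereo = logical(0)))
  }
  mols <- .obMols(smiles)
  props <- ChemmineOB::prop_OB(mols)
  nheavy <- as.integer(ChemmineOB::smartsSearch_OB(mols, "[!#1]"))
  can <- canonicalizeSmiles(smiles)
  data.frame(mw = as.numeric(props$MW), n_heavy = nheavy,
             has_stereo = grepl("@", can, fixed = TRUE))
}

#' Count SMARTS pattern matches per molecule
#'
#' @param smiles character vector of valid SMILES.
#' @param pattern a SMARTS pattern string.
#' @return integer vector of match counts (unique matches).
#' @export
smartsMatches <- function(smiles, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  if (length(smiles) == 0L) return(integer(0))
  mols <- .obMols(smiles)
  counts <- tryCatch(
    ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE),
    error = function(e) stop("unparseable SMARTS pattern: ", pattern))
  counts <- as.integer(counts)
  if (length(counts) != length(smiles) || anyNA(counts)) {
    stop("unparseable SMARTS pattern: ", pattern)
  }
  counts
}

# Organic subset filter support: the element symbols allowed outside
# brackets plus those extracted from bracket atoms.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

.smilesElements <- function(smiles) {
  toks <- tokenizeSmiles(smiles)
  els <- character(0)
  for (tk in toks) {
    if (startsWith(tk, "[")) {
      body <- gsub("^\\[|\\]$", "", tk)
      body <- gsub("@|[0-9]|\\+|-|^H(?=[A-Z])", "", body, perl = TRUE)
      m <- gregexpr("[A-Z][a-z]?|as|se|[bcnops]", body)[[1]]
      if (m[1] != -1L) els <- c(els, regmatches(body, list(m))[[1]])
    } else if (grepl("^(Cl|Br|[A-IK-Za-ik-z])$", tk) &&
               !grepl("^[0-9()=#/\\\\.+%@-]", tk)) {
      els <- c(els, tk)
    }
  }
  unique(ifelse(els %in% c("b", "c", "n", "o", "p", "s"), toupper(els), els))
}

#' MACCS key fingerprints
#'
#' Computes the 166-key MACCS substructure fingerprint for each molecule.
#'
#' @param smiles character vector of valid SMILES.
#' @return binary integer matrix, one row per molecule, 166 columns.
#' @export
maccsFingerprints <- function(smiles) {
  if (length(smiles) == 0L) return(matrix(integer(0), 0, 166))
  mols <- .obMols(smiles)
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1L)   # single molecule
  fp <- fp[, seq_len(166), drop = FALSE]
  storage.mode(fp) <- "integer"
  rownames(fp) <- NULL
  fp
}

#' Extended-connectivity fingerprints (ECFP, radius 2)
#'
#' Circular substructure fingerprints hashed to `bits` positions. The
#' toolkit emits 4096-bit ECFP4 vectors; these are folded by bitwise OR to
#' the requested width (default 2048).
#'
#' @param smiles character vector of valid SMILES.
#' @param bits output width, a divisor of 4096. Default 2048.
#' @return binary integer matrix, one row per molecule.
#' @export
ecfpFingerprints <- function(smiles, bits = 2048L) {
  stopifnot(4096L %% bits == 0L)
  if (length(smiles) == 0L) return(matrix(integer(0), 0, bits))
  mols <- .obMols(smiles)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1L)   # single molecule
  folds <- 4096L %/% bits
  out <- matrix(0L, nrow(fp), bits)
  for (k in seq_len(folds)) {
    out <- out | fp[, ((k - 1L) * bits + 1L):(k * bits), drop = FALSE]
  }
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Generate a randomized SMILES variant
#'
#' SMILES enumeration: rewrites each molecule starting the atom traversal
#' from a randomly chosen atom, producing an alternative surface string for
#' the same molecule. Used to build the random-to-canonical translation
#' pairs. Deterministic for a fixed seed.
#'
#' @param smiles character vector of valid SMILES.
#' @param seed integer seed controlling the random root-atom choice.
#' @return character vector of randomized SMILES, aligned with the input;
#'   each canonicalizes back to the canonical form of its input.
#' @export
enumerateRandomSmiles <- function(smiles, seed) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  nheavy <- molProperties(smiles)$n_heavy
  can <- .obCanonical(smiles)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- rep(NA_character_, n)
  # the toolkit occasionally drops a stereo descriptor for particular
  # roots; draw a fresh root for any molecule whose rewrite no longer
  # canonicalizes to the same structure, then fall back to the input
  for (attempt in 1:3) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    root <- vapply(nheavy[todo], function(k) sample.int(k, 1L), integer(1))
    cand <- rep(NA_character_, length(todo))
    for (r in unique(root)) {
      idx <- which(root == r)
      cand[idx] <- .obRootedSmiles(smiles[todo][idx], r)
    }
    ok <- !is.na(cand) & nzchar(cand)
    if (any(ok)) {
      back <- .obCanonical(cand[ok])
      ok[ok] <- !is.na(back) & back == can[todo][ok]
    }
    out[todo[ok]] <- cand[ok]
  }
  bad <- is.na(out) | !nzchar(out)
  out[bad] <- smiles[bad]
  out
}

# obabel CLI call: rooted SMILES output (-xf) is an output-format option the
# in-process API does not expose.
.obRootedSmiles <- function(smiles, root) {
  ids <- sprintf("t%07d", seq_along(smiles))
  inp <- tempfile(fileext = ".smi")
  outp <- tempfile(fileext = ".smi")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  writeLines(paste(smiles, ids), inp)
  suppressWarnings(system2("obabel",
    c("-ismi", inp, "-osmi", "-O", outp, "-xf", as.character(root)),
    stdout = FALSE, stderr = FALSE))
  res <- rep(NA_character_, length(smiles))
  if (file.exists(outp)) {
    lines <- readLines(outp, warn = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2L && nzchar(p[[1]])) {
        i <- match(trimws(p[[2]]), ids)
        if (!is.na(i)) res[i] <- p[[1]]
      }
    }
  }
  res
}

# Save/restore the global RNG stream so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
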