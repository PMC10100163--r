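# Independent brute-force oracles, kept deliberately naive so they cannot
# share code paths with the package implementation.

# whole-string equality by explicit character loop
oracle_perfect <- function(t, p) {
  hits <- 0
  for (i in seq_along(t)) {
    ti <- strsplit(t[i], "")[[1]]
    pi <- strsplit(p[i], "")[[1]]
    same <- length(ti) == length(pi)
    if (same && length(ti) > 0) {
      for (j in seq_along(ti)) if (ti[j] != pi[j]) { same <- FALSE; break }
    }
    if (same) hits <- hits + 1
  }
  hits / length(t)
}

# per-position agreement by explicit double loop
oracle_partial <- function(t, p) {
  acc <- 0
  for (i in seq_along(t)) {
    ti <- strsplit(t[i], "")[[1]]
    pi <- strsplit(p[i], "")[[1]]
    lt <- length(ti); lp <- length(pi)
    if (lt == 0 && lp == 0) { acc <- acc + 1; next }
    if (min(lt, lp) == 0) next
    m <- 0
    for (j in seq_len(min(lt, lp))) if (ti[j] == pi[j]) m <- m + 1
    acc <- acc + m / max(lt, lp)
  }
  acc / length(t)
}

# naive on-bit set Tanimoto
oracle_tanimoto <- function(a, b) {
  on_a <- which(a != 0); on_b <- which(b != 0)
  inter <- length(intersect(on_a, on_b))
  uni <- length(on_a) + length(on_b) - inter
  if (uni == 0) 1 else inter / uni
}

# random SMILES-like strings (arbitrary characters; the metrics are string
# functions and must not care about chemistry)
random_string_pairs <- function(n, max_len = 60, seed = 1) {
  set.seed(seed)
  alph <- c(LETTERS[1:6], letters[1:6], "(", ")", "=", "#", "1", "2", "[", "]")
  draw <- function() paste(sample(alph, sample(0:max_len, 1), replace = TRUE),
                           collapse = "")
  t <- character(n); p <- character(n)
  for (i in seq_len(n)) {
    t[i] <- draw()
    # half the pairs share a prefix so partial matches actually occur
    p[i] <- if (runif(1) < 0.5) draw() else {
      base <- t[i]
      k <- nchar(base)
      if (k < 2) draw() else paste0(substr(base, 1, sample(k, 1)), draw())
    }
  }
  list(t = t, p = p)
}
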