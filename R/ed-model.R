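# GRU encoder-decoder translating randomized SMILES to canonical SMILES.
# Encoder: 3 stacked GRU layers; the final hidden states of all layers are
# concatenated, perturbed with zero-centered Gaussian noise (training
# only), dropped out, and mapped through a fully connected tanh layer to
# the latent bottleneck. Decoder: a fully connected tanh layer maps the
# latent vector to `decoder_init_width` units, split by layer width to
# initialize a 3-layer GRU stack whose top layer feeds a softmax over the
# vocabulary. Training minimizes padding-masked token-level cross-entropy
# with teacher forcing; decoding is greedy argmax.

#' Model configuration
#'
#' @param encoder_units widths of the three encoder GRU layers (the decoder
#'   stack mirrors them). Default c(256, 512, 1024).
#' @param latent_dim bottleneck width (tanh units). Default 256.
#' @param decoder_init_width width of the latent-to-decoder layer; must
#'   equal `sum(encoder_units)` (default 1792), split per decoder layer in
#'   proportion to the layer widths.
#' @param dropout_rate dropout on each recurrent layer's outputs and on the
#'   concatenated encoder state, training mode only. Default 0.15.
#' @param noise_sd standard deviation of the zero-centered normal noise
#'   added to the concatenated encoder states, training mode only.
#'   Default 0.05.
#' @param max_decode_length greedy-decoding cap; if NA it is set at
#'   training time to 1.5 x the longest training target.
#' @return validated configuration list.
#' @export
modelConfig <- function(encoder_units = c(256L, 512L, 1024L),
                        latent_dim = 256L,
                        decoder_init_width = sum(encoder_units),
                        dropout_rate = 0.15, noise_sd = 0.05,
                        max_decode_length = NA_integer_) {
  stopifnot(length(encoder_units) == 3L, all(encoder_units >= 1L),
            latent_dim >= 1L, dropout_rate >= 0, dropout_rate < 1,
            noise_sd >= 0)
  if (decoder_init_width != sum(encoder_units)) {
    stop("decoder_init_width (", decoder_init_width,
         ") must equal the sum of the decoder layer widths (",
         sum(encoder_units), ")")
  }
  list(encoder_units = as.integer(encoder_units),
       latent_dim = as.integer(latent_dim),
       decoder_init_width = as.integer(decoder_init_width),
       dropout_rate = dropout_rate, noise_sd = noise_sd,
       max_decode_length = as.integer(max_decode_length))
}

#' Training configuration
#'
#' @param learning_rate initial Adam step size. Default 5e-4.
#' @param lr_decay_factor multiplicative learning-rate decay. Default 0.9.
#' @param lr_decay_interval_epochs epochs between decays. Default 250.
#' @param batch_size default 1024.
#' @param checkpoint_epochs sorted integer epochs at which snapshots are
#'   stored; must start with 0 (the untrained negative control). Default
#'   c(0, 6, 13, 104, 260, 338, 598).
#' @param clip_norm global gradient-norm ceiling per update (standard
#'   recurrent-network stabilization). Default 5; Inf disables.
#' @param seed run seed (shuffling, dropout, noise).
#' @export
trainConfig <- function(learning_rate = 5e-4, lr_decay_factor = 0.9,
                        lr_decay_interval_epochs = 250L, batch_size = 1024L,
                        checkpoint_epochs = c(0L, 6L, 13L, 104L, 260L, 338L,
                                              598L),
                        clip_norm = 5, seed = 1L) {
  checkpoint_epochs <- as.integer(checkpoint_epochs)
  stopifnot(learning_rate > 0, lr_decay_factor > 0, lr_decay_factor <= 1,
            lr_decay_interval_epochs >= 1L, batch_size >= 1L,
            clip_norm > 0,
            !is.unsorted(checkpoint_epochs, strictly = TRUE),
            checkpoint_epochs[1] == 0L)
  list(learning_rate = learning_rate, lr_decay_factor = lr_decay_factor,
       lr_decay_interval_epochs = as.integer(lr_decay_interval_epochs),
       batch_size = as.integer(batch_size),
       checkpoint_epochs = checkpoint_epochs, clip_norm = clip_norm,
       seed = as.integer(seed))
}

.clipGrads <- function(g, clip_norm) {
  if (!is.finite(clip_norm)) return(g)
  nrm <- sqrt(sum(vapply(g, function(x) sum(x * x), numeric(1))))
  if (nrm > clip_norm) g <- lapply(g, function(x) x * (clip_norm / nrm))
  g
}

.PAD <- 1L; .SOS <- 2L; .EOS <- 3L; .UNK <- 4L

# uniform(-1/sqrt(H), 1/sqrt(H)) initialization, fan-in on the hidden width
.initMat <- function(nr, nc, h) {
  k <- 1 / sqrt(h)
  matrix(runif(nr * nc, -k, k), nr, nc)
}

#' Build an initialized encoder-decoder model
#'
#' @param config a [modelConfig()].
#' @param vocab the \linkS4class{SmilesVocabulary} the model will speak.
#' @param seed integer; the same seed reproduces identical initial
#'   parameters.
#' @return an \linkS4class{EDModel}.
#' @export
buildEDModel <- function(config, vocab, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  V <- length(vocab)
  H <- config$encoder_units
  L <- config$latent_dim
  p <- list()
  ins <- c(V, H[1], H[2])
  for (l in 1:3) {
    h <- H[l]
    p[[paste0("enc", l, ".W")]] <- .initMat(ins[l], 3L * h, h)
    p[[paste0("enc", l, ".U")]] <- .initMat(h, 3L * h, h)
    p[[paste0("enc", l, ".b")]] <- numeric(3L * h)
    p[[paste0("dec", l, ".W")]] <- .initMat(ins[l], 3L * h, h)
    p[[paste0("dec", l, ".U")]] <- .initMat(h, 3L * h, h)
    p[[paste0("dec", l, ".b")]] <- numeric(3L * h)
  }
  p[["lat.W"]] <- .initMat(sum(H), L, sum(H))
  p[["lat.b"]] <- numeric(L)
  p[["ini.W"]] <- .initMat(L, sum(H), L)
  p[["ini.b"]] <- numeric(sum(H))
  p[["out.W"]] <- .initMat(H[3], V, H[3])
  p[["out.b"]] <- numeric(V)
  mdl <- if (is.na(config$max_decode_length)) 120L else config$max_decode_length
  new("EDModel", params = p, config = config, vocabulary = vocab,
      max_decode_length = as.integer(mdl))
}

.onehotCube <- function(ids, V) {
  B <- nrow(ids); T <- ncol(ids)
  X <- array(0, c(B, V, T))
  X[cbind(rep(seq_len(B), T), as.vector(ids),
          rep(seq_len(T), each = B))] <- 1
  X
}

.padIds <- function(id_list, Tmax = max(vapply(id_list, length, 1L))) {
  B <- length(id_list)
  m <- matrix(.PAD, B, Tmax)
  for (i in seq_len(B)) {
    v <- id_list[[i]]
    if (length(v)) m[i, seq_along(v)] <- v
  }
  m
}

.dropMask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dims)
}

# gather h_{i, , len_i}: each sequence's hidden state at its last real
# token, so trailing padding never reaches the latent code
.gatherLast <- function(Hc, lens) {
  B <- dim(Hc)[1]; H <- dim(Hc)[2]
  out <- matrix(0, B, H)
  for (i in seq_len(B)) out[i, ] <- Hc[i, , lens[i]]
  out
}

.scatterLast <- function(dims, rows, lens) {
  out <- array(0, dims)
  for (i in seq_len(dims[1])) out[i, , lens[i]] <- rows[i, ]
  out
}

.applyMask <- function(x, mask) if (is.null(mask)) x else x * mask

# Forward + backward over one teacher-forced batch. Returns the mean
# per-token cross-entropy and the gradient list (train mode), or just the
# loss (train_mode = FALSE evaluates without noise/dropout).
.batchGrad <- function(p, cfg, src, tgt_in, tgt_out, train_mode = TRUE,
                       want_grad = TRUE) {
  B <- nrow(src); Ts <- ncol(src); Td <- ncol(tgt_in)
  V <- ncol(p[["out.W"]]); H <- cfg$encoder_units
  rate <- if (train_mode) cfg$dropout_rate else 0

  X1 <- .onehotCube(src, V)
  z0 <- function(h) matrix(0, B, h)
  f1 <- cpp_gru_forward(X1, z0(H[1]), p[["enc1.W"]], p[["enc1.U"]],
                        p[["enc1.b"]])
  D1e <- .dropMask(dim(f1$H), rate); H1d <- .applyMask(f1$H, D1e)
  f2 <- cpp_gru_forward(H1d, z0(H[2]), p[["enc2.W"]], p[["enc2.U"]],
                        p[["enc2.b"]])
  D2e <- .dropMask(dim(f2$H), rate); H2d <- .applyMask(f2$H, D2e)
  f3 <- cpp_gru_forward(H2d, z0(H[3]), p[["enc3.W"]], p[["enc3.U"]],
                        p[["enc3.b"]])

  lens <- pmax(1L, rowSums(src != .PAD))
  C <- cbind(.gatherLast(f1$H, lens), .gatherLast(f2$H, lens),
             .gatherLast(f3$H, lens))
  if (train_mode && cfg$noise_sd > 0) {
    C <- C + matrix(rnorm(length(C), sd = cfg$noise_sd), nrow(C))
  }
  Dc <- if (rate > 0) matrix((runif(length(C)) >= rate) / (1 - rate),
                             nrow(C)) else NULL
  Cd <- .applyMask(C, Dc)
  z <- tanh(sweep(Cd %*% p[["lat.W"]], 2, p[["lat.b"]], "+"))
  a <- tanh(sweep(z %*% p[["ini.W"]], 2, p[["ini.b"]], "+"))
  sp <- c(0L, cumsum(H))
  h0 <- lapply(1:3, function(l) a[, (sp[l] + 1L):sp[l + 1L], drop = FALSE])

  Xd <- .onehotCube(tgt_in, V)
  g1 <- cpp_gru_forward(Xd, h0[[1]], p[["dec1.W"]], p[["dec1.U"]],
                        p[["dec1.b"]])
  D1d <- .dropMask(dim(g1$H), rate); G1d <- .applyMask(g1$H, D1d)
  g2 <- cpp_gru_forward(G1d, h0[[2]], p[["dec2.W"]], p[["dec2.U"]],
                        p[["dec2.b"]])
  D2d <- .dropMask(dim(g2$H), rate); G2d <- .applyMask(g2$H, D2d)
  g3 <- cpp_gru_forward(G2d, h0[[3]], p[["dec3.W"]], p[["dec3.U"]],
                        p[["dec3.b"]])
  D3d <- .dropMask(dim(g3$H), rate); G3d <- .applyMask(g3$H, D3d)

  M <- matrix(aperm(G3d, c(1, 3, 2)), B * Td, H[3])
  logits <- sweep(M %*% p[["out.W"]], 2, p[["out.b"]], "+")
  tv <- as.vector(tgt_out)                     # row (t-1)*B + b order
  mask <- tv != .PAD
  nm <- sum(mask)
  mx <- logits[cbind(seq_len(nrow(logits)),
                     max.col(logits, ties.method = "first"))]
  ex <- exp(logits - mx)
  P <- ex / rowSums(ex)
  picked <- P[cbind(seq_len(nrow(P)), tv)]
  loss <- -sum(log(pmax(picked[mask], 1e-300))) / nm
  if (!is.finite(loss)) stop("non-finite training loss (batch of ", B,
                             " at target length ", Td, ")")
  if (!want_grad) return(list(loss = loss, n_tokens = nm))

  dlog <- P
  dlog[cbind(seq_len(nrow(P)), tv)] <- dlog[cbind(seq_len(nrow(P)), tv)] - 1
  dlog[!mask, ] <- 0
  dlog <- dlog / nm
  g <- list()
  g[["out.W"]] <- crossprod(M, dlog)
  g[["out.b"]] <- colSums(dlog)
  dM <- tcrossprod(dlog, p[["out.W"]])
  dG3 <- .applyMask(aperm(array(dM, c(B, Td, H[3])), c(1, 3, 2)), D3d)

  b3 <- cpp_gru_backward(G2d, h0[[3]], p[["dec3.W"]], p[["dec3.U"]],
                         g3$H, g3$Z, g3$R, g3$N, g3$HUn, dG3)
  dG2 <- .applyMask(b3$dX, D2d)
  b2 <- cpp_gru_backward(G1d, h0[[2]], p[["dec2.W"]], p[["dec2.U"]],
                         g2$H, g2$Z, g2$R, g2$N, g2$HUn, dG2)
  dG1 <- .applyMask(b2$dX, D1d)
  b1 <- cpp_gru_backward(Xd, h0[[1]], p[["dec1.W"]], p[["dec1.U"]],
                         g1$H, g1$Z, g1$R, g1$N, g1$HUn, dG1)
  for (l in 1:3) {
    bl <- list(b1, b2, b3)[[l]]
    g[[paste0("dec", l, ".W")]] <- bl$dW
    g[[paste0("dec", l, ".U")]] <- bl$dU
    g[[paste0("dec", l, ".b")]] <- as.numeric(bl$db)
  }

  da <- cbind(b1$dh0, b2$dh0, b3$dh0)
  dA0 <- da * (1 - a * a)
  g[["ini.W"]] <- crossprod(z, dA0)
  g[["ini.b"]] <- colSums(dA0)
  dz <- tcrossprod(dA0, p[["ini.W"]])
  dZp <- dz * (1 - z * z)
  g[["lat.W"]] <- crossprod(Cd, dZp)
  g[["lat.b"]] <- colSums(dZp)
  dC <- .applyMask(tcrossprod(dZp, p[["lat.W"]]), Dc)

  dH3 <- .scatterLast(dim(f3$H), dC[, (sp[3] + 1L):sp[4], drop = FALSE],
                      lens)
  e3 <- cpp_gru_backward(H2d, z0(H[3]), p[["enc3.W"]], p[["enc3.U"]],
                         f3$H, f3$Z, f3$R, f3$N, f3$HUn, dH3)
  dH2 <- .applyMask(e3$dX, D2e) +
    .scatterLast(dim(f2$H), dC[, (sp[2] + 1L):sp[3], drop = FALSE], lens)
  e2 <- cpp_gru_backward(H1d, z0(H[2]), p[["enc2.W"]], p[["enc2.U"]],
                         f2$H, f2$Z, f2$R, f2$N, f2$HUn, dH2)
  dH1 <- .applyMask(e2$dX, D1e) +
    .scatterLast(dim(f1$H), dC[, (sp[1] + 1L):sp[2], drop = FALSE], lens)
  e1 <- cpp_gru_backward(X1, z0(H[1]), p[["enc1.W"]], p[["enc1.U"]],
                         f1$H, f1$Z, f1$R, f1$N, f1$HUn, dH1)
  for (l in 1:3) {
    el <- list(e1, e2, e3)[[l]]
    g[[paste0("enc", l, ".W")]] <- el$dW
    g[[paste0("enc", l, ".U")]] <- el$dU
    g[[paste0("enc", l, ".b")]] <- as.numeric(el$db)
  }
  list(loss = loss, n_tokens = nm, grads = g)
}

.adamInit <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

.adamStep <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(p = p, st = st)
}

#' Train the encoder-decoder and collect scheduled checkpoints
#'
#' Teacher-forced training on the corpus's random-to-canonical pairs, with
#' padding-masked token cross-entropy, Adam, the configured step-decay
#' learning-rate schedule, and per-epoch bucket-shuffled batches (batches
#' never mix buckets). A snapshot of the parameters is stored at every
#' epoch listed in `train_config$checkpoint_epochs`; epoch 0 is the
#' untrained model.
#'
#' @param model an \linkS4class{EDModel} from [buildEDModel()].
#' @param corpus a \linkS4class{SmilesCorpus}.
#' @param train_config a [trainConfig()].
#' @param verbose print per-epoch loss.
#' @return a \linkS4class{CheckpointSet} (accuracies unset; see
#'   [evaluateModelSet()]).
#' @export
trainEDModel <- function(model, corpus, train_config, verbose = FALSE) {
  stopifnot(is(model, "EDModel"), is(corpus, "SmilesCorpus"))
  n <- length(corpus@source_ids)
  if (n == 0L) stop("empty corpus")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(train_config$seed)

  tgt_in <- lapply(corpus@target_ids, function(v) c(.SOS, v))
  tgt_out <- lapply(corpus@target_ids, function(v) c(v, .EOS))
  max_tgt <- max(vapply(corpus@target_ids, length, 1L))
  model@max_decode_length <- as.integer(ceiling(1.5 * (max_tgt + 1L)))

  cfg <- model@config
  p <- model@params
  st <- .adamInit(p)
  ck_epochs <- train_config$checkpoint_epochs
  n_epochs <- max(ck_epochs)
  snaps <- list()
  snapshot <- function(params) {
    m <- model; m@params <- params; m
  }
  if (0L %in% ck_epochs) snaps[["0"]] <- snapshot(p)
  loss_log <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  by_bucket <- split(seq_len(n), corpus@bucket)

  for (epoch in seq_len(n_epochs)) {
    lr <- train_config$learning_rate *
      train_config$lr_decay_factor ^
        ((epoch - 1L) %/% train_config$lr_decay_interval_epochs)
    batches <- list()
    for (idx in by_bucket) {
      idx <- idx[sample.int(length(idx))]
      starts <- seq(1L, length(idx), by = train_config$batch_size)
      for (s in starts) {
        batches[[length(batches) + 1L]] <-
          idx[s:min(s + train_config$batch_size - 1L, length(idx))]
      }
    }
    batches <- batches[sample.int(length(batches))]
    tot_loss <- 0; tot_tok <- 0
    for (bi in batches) {
      src <- .padIds(corpus@source_ids[bi])
      ti <- .padIds(tgt_in[bi])
      to <- .padIds(tgt_out[bi])
      r <- .batchGrad(p, cfg, src, ti, to, train_mode = TRUE)
      up <- .adamStep(p, .clipGrads(r$grads, train_config$clip_norm), st, lr)
      p <- up$p; st <- up$st
      tot_loss <- tot_loss + r$loss * r$n_tokens
      tot_tok <- tot_tok + r$n_tokens
    }
    loss_log <- rbind(loss_log,
                      data.frame(epoch = epoch,
                                 mean_loss = tot_loss / tot_tok))
    if (verbose) message("epoch ", epoch, " mean loss ",
                         sprintf("%.4f", tot_loss / tot_tok))
    if (epoch %in% ck_epochs) snaps[[as.character(epoch)]] <- snapshot(p)
  }
  kept <- ck_epochs[ck_epochs <= n_epochs]
  new("CheckpointSet", epochs = kept,
      models = unname(snaps[as.character(kept)]),
      accuracy = rep(NA_real_, length(kept)), loss_log = loss_log)
}

#' Teacher-forced loss on a corpus (evaluation mode)
#'
#' @param model an \linkS4class{EDModel}.
#' @param corpus a \linkS4class{SmilesCorpus}.
#' @return mean per-token cross-entropy without noise or dropout.
#' @export
teacherForcedLoss <- function(model, corpus) {
  tgt_in <- lapply(corpus@target_ids, function(v) c(.SOS, v))
  tgt_out <- lapply(corpus@target_ids, function(v) c(v, .EOS))
  tot <- 0; ntok <- 0
  idx <- split(seq_along(corpus@source_ids),
               ceiling(seq_along(corpus@source_ids) / 256))
  for (bi in idx) {
    r <- .batchGrad(model@params, model@config, .padIds(corpus@source_ids[bi]),
                    .padIds(tgt_in[bi]), .padIds(tgt_out[bi]),
                    train_mode = FALSE, want_grad = FALSE)
    tot <- tot + r$loss * r$n_tokens
    ntok <- ntok + r$n_tokens
  }
  tot / ntok
}

# tokenize + index a SMILES vector under the model vocabulary
.modelIds <- function(model, smiles) {
  lapply(smiles, function(s)
    encodeTokens(model@vocabulary, tokenizeSmiles(s), strict = TRUE))
}

#' Extract latent descriptors
#'
#' Feeds SMILES through the encoder in evaluation mode (no dropout, no
#' noise) and returns the tanh bottleneck activations: the model's learned
#' molecular descriptor. Deterministic; every entry lies in (-1, 1).
#'
#' @param model an \linkS4class{EDModel}.
#' @param smiles character vector; must tokenize within the model
#'   vocabulary (an out-of-vocabulary token is an error naming the token).
#' @param batch_size molecules per forward pass.
#' @return numeric matrix, one row per molecule, `latent_dim` columns.
#' @export
encodeMolecules <- function(model, smiles, batch_size = 256L) {
  ids <- .modelIds(model, smiles)
  p <- model@params; cfg <- model@config
  H <- cfg$encoder_units; V <- length(model@vocabulary)
  out <- matrix(NA_real_, length(smiles), cfg$latent_dim)
  for (bi in split(seq_along(ids), ceiling(seq_along(ids) / batch_size))) {
    src <- .padIds(ids[bi])
    B <- nrow(src); Ts <- ncol(src)
    X1 <- .onehotCube(src, V)
    f1 <- cpp_gru_forward(X1, matrix(0, B, H[1]), p[["enc1.W"]],
                          p[["enc1.U"]], p[["enc1.b"]])
    f2 <- cpp_gru_forward(f1$H, matrix(0, B, H[2]), p[["enc2.W"]],
                          p[["enc2.U"]], p[["enc2.b"]])
    f3 <- cpp_gru_forward(f2$H, matrix(0, B, H[3]), p[["enc3.W"]],
                          p[["enc3.U"]], p[["enc3.b"]])
    lens <- pmax(1L, rowSums(src != .PAD))
    C <- cbind(.gatherLast(f1$H, lens), .gatherLast(f2$H, lens),
               .gatherLast(f3$H, lens))
    out[bi, ] <- tanh(sweep(C %*% p[["lat.W"]], 2, p[["lat.b"]], "+"))
  }
  out
}

#' Greedy decoding from latent vectors
#'
#' Emits the argmax token at each step until the end-of-sequence symbol or
#' `max_decode_length`, then detokenizes. The result may be an invalid
#' SMILES string; validity is judged downstream. Truncated sequences are
#' flagged in the `truncated` attribute, not raised.
#'
#' @param model an \linkS4class{EDModel}.
#' @param latent numeric matrix (rows = molecules, `latent_dim` columns) or
#'   a single latent vector.
#' @return character vector of decoded strings.
#' @export
decodeGreedy <- function(model, latent) {
  if (is.null(dim(latent))) latent <- matrix(latent, 1L)
  cfg <- model@config
  if (ncol(latent) != cfg$latent_dim) {
    stop("latent width ", ncol(latent), " does not match latent_dim ",
         cfg$latent_dim)
  }
  p <- model@params; H <- cfg$encoder_units; V <- length(model@vocabulary)
  B <- nrow(latent)
  a <- tanh(sweep(latent %*% p[["ini.W"]], 2, p[["ini.b"]], "+"))
  sp <- c(0L, cumsum(H))
  h <- lapply(1:3, function(l) a[, (sp[l] + 1L):sp[l + 1L], drop = FALSE])
  cur <- rep(.SOS, B)
  done <- logical(B)
  toks <- matrix(.PAD, B, model@max_decode_length)
  for (step in seq_len(model@max_decode_length)) {
    X <- matrix(0, B, V); X[cbind(seq_len(B), cur)] <- 1
    h[[1]] <- cpp_gru_cell(X, h[[1]], p[["dec1.W"]], p[["dec1.U"]],
                           p[["dec1.b"]])
    h[[2]] <- cpp_gru_cell(h[[1]], h[[2]], p[["dec2.W"]], p[["dec2.U"]],
                           p[["dec2.b"]])
    h[[3]] <- cpp_gru_cell(h[[2]], h[[3]], p[["dec3.W"]], p[["dec3.U"]],
                           p[["dec3.b"]])
    logits <- sweep(h[[3]] %*% p[["out.W"]], 2, p[["out.b"]], "+")
    nxt <- max.col(logits, ties.method = "first")
    nxt[done] <- .PAD
    done <- done | nxt == .EOS
    toks[, step] <- nxt
    cur <- nxt
    cur[cur == .PAD] <- .EOS   # keep feeding a terminal symbol once done
    if (all(done)) break
  }
  res <- vapply(seq_len(B), function(i) {
    v <- toks[i, ]
    stop_at <- match(.EOS, v)
    v <- if (is.na(stop_at)) v else v[seq_len(stop_at - 1L)]
    v <- v[!(v %in% c(.PAD, .SOS, .UNK, .EOS))]
    detokenizeSmiles(decodeTokens(model@vocabulary, v))
  }, character(1))
  attr(res, "truncated") <- !vapply(seq_len(B), function(i)
    .EOS %in% toks[i, ], logical(1))
  res
}

#' Translate SMILES through the model
#'
#' Encode then greedily decode each molecule, preserving order.
#'
#' @param model an \linkS4class{EDModel}.
#' @param smiles character vector of input SMILES (the translation source,
#'   typically randomized SMILES).
#' @param batch_size molecules per pass.
#' @return data.frame with columns `input` and `predicted`.
#' @export
translateSet <- function(model, smiles, batch_size = 256L) {
  if (length(smiles) == 0L) {
    return(data.frame(input = character(0), predicted = character(0)))
  }
  z <- encodeMolecules(model, smiles, batch_size = batch_size)
  pred <- character(length(smiles))
  for (bi in split(seq_along(smiles), ceiling(seq_along(smiles) / batch_size))) {
    pred[bi] <- decodeGreedy(model, z[bi, , drop = FALSE])
  }
  data.frame(input = smiles, predicted = pred, stringsAsFactors = FALSE)
}
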