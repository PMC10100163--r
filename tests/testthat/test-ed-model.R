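# Encoder-decoder model: configuration rules, gradients, determinism,
# encoding/decoding contracts, memorization.

test_that("model configuration enforces the width consistency rule", {
  cfg <- modelConfig()
  expect_equal(sum(cfg$encoder_units), 1792L)    # 256 + 512 + 1024
  expect_equal(cfg$decoder_init_width, 1792L)
  expect_equal(cfg$latent_dim, 256L)
  small <- modelConfig(encoder_units = c(32L, 64L, 128L), latent_dim = 32L,
                       decoder_init_width = 224L)
  expect_equal(small$decoder_init_width, 224L)
  expect_error(modelConfig(encoder_units = c(32L, 64L, 128L),
                           decoder_init_width = 200L), "sum")
})

test_that("parameter initialization is deterministic under a seed", {
  vocab <- buildVocabulary(list(c("C", "O", "N", "(", ")", "1", "=")))
  cfg <- modelConfig(encoder_units = c(8L, 10L, 12L), latent_dim = 6L,
                     decoder_init_width = 30L)
  m1 <- buildEDModel(cfg, vocab, seed = 11)
  m2 <- buildEDModel(cfg, vocab, seed = 11)
  expect_identical(m1@params, m2@params)
  m3 <- buildEDModel(cfg, vocab, seed = 12)
  expect_false(identical(m1@params, m3@params))
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("edsmiles")
  bg <- get(".batchGrad", ns); padIds <- get(".padIds", ns)
  set.seed(42)
  vocab <- buildVocabulary(list(c("C", "O", "N", "(", ")", "1", "=")))
  cfg <- modelConfig(encoder_units = c(4L, 5L, 6L), latent_dim = 3L,
                     decoder_init_width = 15L, dropout_rate = 0,
                     noise_sd = 0)
  m <- buildEDModel(cfg, vocab, seed = 7)
  p <- m@params
  src <- matrix(c(5L, 6L, 7L, 1L, 6L, 6L, 5L, 9L), nrow = 2, byrow = TRUE)
  tgt <- list(c(5L, 6L, 7L), c(6L, 5L))
  ti <- padIds(lapply(tgt, function(v) c(2L, v)))
  to <- padIds(lapply(tgt, function(v) c(v, 3L)))
  r <- bg(p, cfg, src, ti, to, train_mode = FALSE, want_grad = TRUE)
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- bg(p2, cfg, src, ti, to, FALSE, FALSE)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- bg(p2, cfg, src, ti, to, FALSE, FALSE)$loss
      num <- (l1 - l0) / (2 * eps)
      ana <- r$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-5 + 1e-3 * (abs(num) + abs(ana)))
    }
  }
})

test_that("descriptor extraction is deterministic, bounded and batch-invariant", {
  memo <- fx_memo()
  mdl <- memo$fit
  sm <- memo$records$canonical_smiles
  z1 <- encodeMolecules(mdl, sm)
  z2 <- encodeMolecules(mdl, sm)
  expect_identical(z1, z2)                       # bitwise repeatable
  expect_equal(ncol(z1), 32L)
  expect_lt(max(abs(z1)), 1)                     # tanh range
  # the latent code of a molecule does not depend on its batch companions
  z_solo <- encodeMolecules(mdl, sm[1])
  expect_equal(z_solo[1, ], z1[1, ], tolerance = 1e-12)
  expect_error(encodeMolecules(mdl, "[Xe]"), "\\[Xe\\]")
})

test_that("greedy decoding is total and checks the latent width", {
  vocab <- buildVocabulary(list(c("C", "O", "N", "(", ")", "1", "=")))
  cfg <- modelConfig(encoder_units = c(8L, 10L, 12L), latent_dim = 6L,
                     decoder_init_width = 30L)
  m <- buildEDModel(cfg, vocab, seed = 3)        # untrained
  out <- decodeGreedy(m, rep(0.1, 6))
  expect_type(out, "character")                  # arbitrary content, no error
  expect_error(decodeGreedy(m, rep(0.1, 5)), "latent")
  tr <- translateSet(m, character(0))
  expect_equal(nrow(tr), 0L)
  tr2 <- translateSet(m, c("CCO", "OCC", "NCC"))
  expect_equal(nrow(tr2), 3L)                    # mapping contract
  expect_identical(tr2$input, c("CCO", "OCC", "NCC"))
})

test_that("a small model memorizes 50 short molecules", {
  memo <- fx_memo()
  expect_equal(length(checkpointEpochs(memo$checkpoints)), 3L)
  expect_lt(teacherForcedLoss(memo$fit, memo$corpus), 0.05)
  tr <- translateSet(memo$fit, memo$records$random_smiles)
  expect_equal(perfectAccuracy(memo$records$canonical_smiles, tr$predicted),
               1.0)
  # decode(encode(s)) recovers the canonical string molecule by molecule
  z <- encodeMolecules(memo$fit, memo$records$random_smiles)
  dec <- decodeGreedy(memo$fit, z)
  expect_identical(as.character(dec), memo$records$canonical_smiles)
  # loss descends on memorizable data
  log <- memo$checkpoints@loss_log
  expect_lt(log$mean_loss[log$epoch == 5], log$mean_loss[log$epoch == 1])
})

test_that("training without noise and dropout is exactly repeatable", {
  rec <- fx_molecules(60, seed = 13)
  corp <- prepareCorpus(rec, seed = 5)
  cfg <- modelConfig(encoder_units = c(8L, 10L, 12L), latent_dim = 6L,
                     decoder_init_width = 30L, dropout_rate = 0,
                     noise_sd = 0)
  tc <- trainConfig(learning_rate = 3e-3, batch_size = 20L,
                    checkpoint_epochs = c(0L, 2L), seed = 17)
  run <- function() {
    m <- buildEDModel(cfg, vocabulary(corp), seed = 9)
    trainEDModel(m, corp, tc)
  }
  ck1 <- run(); ck2 <- run()
  expect_identical(checkpointModels(ck1)[[2]]@params,
                   checkpointModels(ck2)[[2]]@params)
  expect_identical(ck1@loss_log, ck2@loss_log)
})

test_that("an untrained checkpoint cannot match whole strings", {
  memo <- fx_memo()
  m0 <- checkpointModels(memo$checkpoints)[[1]]
  tr <- translateSet(m0, memo$records$random_smiles)
  expect_lte(perfectAccuracy(memo$records$canonical_smiles, tr$predicted),
             0.01)
})
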