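# Shared fixtures, built once per test run and cached. All seeds fixed:
# they define the desk-scale study conditions.

.fx <- new.env(parent = emptyenv())

fx_molecules <- function(n = 150, seed = 11, range = c(3L, 20L),
                         stereo = 0) {
  key <- paste("mol", n, seed, range[1], range[2], stereo, sep = "_")
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- generateMolecules(generatorConfig(
      n, heavy_atom_range = range, stereo_fraction = stereo, seed = seed))
  }
  .fx[[key]]
}

# memorization fixture: a small model overfit on 50 short molecules
fx_memo <- function() {
  if (is.null(.fx$memo)) {
    rec <- generateMolecules(generatorConfig(
      50, heavy_atom_range = c(3L, 10L), stereo_fraction = 0, seed = 11))
    corp <- prepareCorpus(rec, boundaries = c(12L, 24L), seed = 2)
    cfg <- modelConfig(encoder_units = c(32L, 64L, 128L), latent_dim = 32L,
                       decoder_init_width = 224L, dropout_rate = 0,
                       noise_sd = 0)
    mdl <- buildEDModel(cfg, vocabulary(corp), seed = 5)
    tc <- trainConfig(learning_rate = 5e-3, batch_size = 25L,
                      checkpoint_epochs = c(0L, 150L, 300L), seed = 3)
    ck <- trainEDModel(mdl, corp, tc)
    .fx$memo <- list(records = rec, corpus = corp, checkpoints = ck,
                     fit = checkpointModels(ck)[[length(ck@epochs)]])
  }
  .fx$memo
}

# the desk-scale learning-progress experiment: 2000 training molecules of
# 3-12 heavy atoms, five replicate held-out sets of 300, checkpoints at
# epochs 0,1,2,5,10,20,40
fx_trend <- function() {
  if (is.null(.fx$trend)) {
    rec <- generateMolecules(generatorConfig(
      3500, heavy_atom_range = c(3L, 12L), seed = 101))
    train_rec <- rec[1:2000, ]
    eval_sets <- lapply(0:4, function(k)
      rec[(2001 + 300 * k):(2300 + 300 * k), ])
    corp <- prepareCorpus(train_rec, seed = 7)
    cfg <- modelConfig(encoder_units = c(32L, 64L, 128L), latent_dim = 96L,
                       decoder_init_width = 224L)
    mdl <- buildEDModel(cfg, vocabulary(corp), seed = 5)
    tc <- trainConfig(learning_rate = 8e-3, lr_decay_factor = 0.5,
                      lr_decay_interval_epochs = 8L, batch_size = 16L,
                      checkpoint_epochs = c(0L, 1L, 2L, 5L, 10L, 20L, 40L),
                      seed = 3)
    ck <- trainEDModel(mdl, corp, tc)
    ev <- evaluateModelSet(ck, eval_sets,
                           train_smiles = train_rec$canonical_smiles)
    # the substructure/misprediction analyses use the first replicate set
    translations <- lapply(checkpointModels(ev$checkpoints), function(m)
      translateSet(m, eval_sets[[1]]$random_smiles))
    .fx$trend <- list(train = train_rec, eval = eval_sets[[1]],
                      eval_sets = eval_sets, corpus = corp,
                      checkpoints = ev$checkpoints, report = ev$report,
                      translations = translations)
  }
  .fx$trend
}
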