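# Synthetic molecule generator and rule-based labels.

test_that("generated molecules respect bounds, validity and uniqueness", {
  cfg <- generatorConfig(100, heavy_atom_range = c(3L, 20L),
                         stereo_fraction = 0, seed = 7)
  rec <- generateMolecules(cfg)
  expect_equal(nrow(rec), 100L)
  expect_true(all(smilesIsValid(rec$canonical_smiles)))
  expect_true(all(rec$n_heavy >= 3L & rec$n_heavy <= 20L))
  expect_false(any(duplicated(rec$canonical_smiles)))
  # every record survives the corpus filter unchanged
  f <- filterChemicals(rec$canonical_smiles, heavy_range = c(3L, 20L))
  expect_equal(nrow(f$kept), 100L)
  expect_identical(f$kept$canonical_smiles, rec$canonical_smiles)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generatorConfig(100, heavy_atom_range = c(3L, 20L),
                         stereo_fraction = 0.2, seed = 7)
  expect_identical(generateMolecules(cfg), generateMolecules(cfg))
})

test_that("stereo fraction is honored within binomial slack", {
  cfg <- generatorConfig(500, stereo_fraction = 0.3, seed = 1)
  rec <- generateMolecules(cfg)
  frac <- mean(grepl("@", rec$canonical_smiles, fixed = TRUE))
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
  expect_true(all(rec$has_stereo ==
                    grepl("@", rec$canonical_smiles, fixed = TRUE)))
})

test_that("an impossible request exhausts the attempt budget with an error", {
  cfg <- generatorConfig(50, heavy_atom_range = c(3L, 4L), seed = 2)
  expect_error(generateMolecules(cfg), "attempt budget")
})

test_that("noiseless labels follow the substructure rule exactly", {
  lc <- labelConfig(rule_substructure = "[OX2H]", noise_rate = 0)
  labels <- generateLabels(c("CCO", "CCC"), lc)  # ethanol, propane
  expect_identical(as.integer(labels), c(1L, 0L))
  expect_error(generateLabels(character(0), lc), "empty")
  expect_error(generateLabels("CCO",
                              labelConfig(rule_substructure = "[[bad")),
               "SMARTS|pattern")
})

test_that("a rule matching nothing yields all-zero labels and a warning", {
  lc <- labelConfig(rule_substructure = "[F]", noise_rate = 0)
  expect_warning(labels <- generateLabels(c("CCO", "CCC"), lc),
                 "matches no molecule")
  expect_identical(as.integer(labels), c(0L, 0L))
})

test_that("label noise is recovered at the configured rate", {
  rec <- fx_molecules(1000, seed = 21)
  clean <- generateLabels(rec, labelConfig(noise_rate = 0, seed = 3))
  noisy <- generateLabels(rec, labelConfig(noise_rate = 0.1, seed = 3))
  flip <- mean(clean != noisy)
  # binomial slack: 0.10 +/- 0.03 covers > 3 standard errors at n = 1000
  expect_gte(flip, 0.07)
  expect_lte(flip, 0.13)
  pf <- attr(noisy, "base_positive_fraction")
  expect_gte(pf, 0.05)
})

test_that("the default corpus keeps the probe rule learnable and balanced", {
  rec <- fx_molecules(500, seed = 31, range = c(3L, 50L))
  base <- mean(smartsMatches(rec$canonical_smiles, "[OX2H]") > 0)
  expect_gte(base, 0.2)
  expect_lte(base, 0.5)
})

test_that("label tables are written as id,smiles,label CSV", {
  rec <- fx_molecules(20, seed = 13)
  labels <- generateLabels(rec, labelConfig(noise_rate = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLabels(rec, labels, path)
  back <- read.csv(path)
  expect_identical(names(back), c("id", "smiles", "label"))
  expect_identical(back$label, as.integer(labels))
})
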