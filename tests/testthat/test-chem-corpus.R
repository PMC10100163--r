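# Corpus preparation: tokenizer, canonicalization, enumeration, filter,
# bucketing, vocabulary.

test_that("tokenizer keeps multi-character atoms and bracket atoms whole", {
  expect_equal(tokenizeSmiles("CCl"), c("C", "Cl"))
  expect_equal(tokenizeSmiles("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_equal(tokenizeSmiles("[C@@H](O)C"),
               c("[C@@H]", "(", "O", ")", "C"))
  expect_equal(tokenizeSmiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_error(tokenizeSmiles("C[Zn"), "tokenize")
})

test_that("tokenize/detokenize is the identity on generated molecules", {
  rec <- fx_molecules(100, seed = 11, stereo = 0.3)
  for (s in rec$canonical_smiles) {
    expect_identical(detokenizeSmiles(tokenizeSmiles(s)), s)
  }
})

test_that("canonicalization is idempotent and merges equivalent writings", {
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  rec <- fx_molecules(80, seed = 11, stereo = 0.3)
  once <- canonicalizeSmiles(rec$canonical_smiles)
  expect_identical(canonicalizeSmiles(once), once)
  # stereo descriptors survive canonicalization
  stereo <- rec$canonical_smiles[rec$has_stereo]
  expect_true(length(stereo) > 0)
  expect_true(all(grepl("@", canonicalizeSmiles(stereo))))
  expect_error(canonicalizeSmiles("C(("), "unparseable")
})

test_that("random enumeration preserves the molecule and is seeded", {
  rec <- fx_molecules(150, seed = 11, stereo = 0.2)
  s <- rec$canonical_smiles
  for (seed in c(1, 2, 3)) {
    r <- enumerateRandomSmiles(s, seed = seed)
    expect_identical(canonicalizeSmiles(r), canonicalizeSmiles(s))
  }
  expect_identical(enumerateRandomSmiles(s, seed = 9),
                   enumerateRandomSmiles(s, seed = 9))
  # a 3-atom molecule admits at least two surface forms across seeds
  variants <- unique(vapply(1:20, function(k)
    enumerateRandomSmiles("CCO", seed = k), character(1)))
  expect_gte(length(variants), 2)
})

test_that("the corpus filter applies parse, salt strip, organic and range rules", {
  f <- filterChemicals(c("CC", "CC[Si](C)C", "[Na+].CC(=O)[O-]", "CCO",
                         "not_a_smiles["))
  expect_equal(f$rejected$reason[f$rejected$smiles == "CC"], "too_small")
  expect_equal(f$rejected$reason[f$rejected$smiles == "CC[Si](C)C"],
               "inorganic")
  expect_equal(f$rejected$reason[f$rejected$smiles == "not_a_smiles["],
               "unparseable")
  # salt stripped to the acetate fragment: 4 heavy atoms, organic, kept
  acet <- f$kept[f$kept$id == "M3", ]
  expect_equal(acet$n_heavy, 4L)
  expect_identical(acet$canonical_smiles,
                   canonicalizeSmiles("CC(=O)[O-]"))
  # largest-fragment choice agrees with a direct toolkit comparison
  frags <- strsplit("[Na+].CC(=O)[O-]", ".", fixed = TRUE)[[1]]
  heavies <- molProperties(frags)$n_heavy
  expect_identical(acet$canonical_smiles,
                   canonicalizeSmiles(frags[which.max(heavies)]))
})

test_that("heavy-atom bounds are inclusive and the filter is pure", {
  # propane (3 heavy atoms) sits on the lower boundary and is kept
  f <- filterChemicals(c("CCC", "CCCC"), heavy_range = c(3L, 4L))
  expect_equal(nrow(f$kept), 2L)
  f2 <- filterChemicals(c("CCC", "CCCC"), heavy_range = c(3L, 4L))
  expect_identical(f, f2)
  f3 <- filterChemicals("CCCCC", heavy_range = c(3L, 4L))
  expect_equal(f3$rejected$reason, "too_large")
})

test_that("bucketing partitions pairs by target length and stereo content", {
  toks <- list(rep("C", 5), rep("C", 15), rep("C", 25),
               c(rep("C", 12), "[C@H]"), rep("C", 50))
  expect_warning(bk <- bucketPairs(toks, boundaries = c(10L, 20L, 40L)),
                 "overflow")
  lab <- bk$labels[as.character(bk$bucket)]
  expect_match(lab[1], "^len1-10$")
  expect_match(lab[2], "^len11-20$")   # length 15 -> second length bucket
  expect_match(lab[3], "^len21-40$")
  expect_match(lab[4], "stereo")       # "@" token forces the stereo sub-bucket
  expect_match(lab[5], "leninf|len41-inf")
  # partition: every pair in exactly one bucket
  expect_equal(length(bk$bucket), length(toks))
  expect_equal(sum(table(bk$bucket)), length(toks))
})

test_that("vocabulary round-trips and covers a same-generator evaluation split", {
  rec <- fx_molecules(150, seed = 11, stereo = 0.2)
  corp <- prepareCorpus(rec[1:100, ], seed = 3)
  vocab <- vocabulary(corp)
  toks <- tokenizeSmiles(rec$canonical_smiles[5])
  expect_identical(decodeTokens(vocab, encodeTokens(vocab, toks)), toks)
  expect_error(encodeTokens(vocab, "[Xe]"), "\\[Xe\\]")
  # held-out molecules from the same generator stay in-vocabulary
  held <- rec[101:150, ]
  for (s in c(held$canonical_smiles, held$random_smiles)) {
    expect_silent(encodeTokens(vocab, tokenizeSmiles(s)))
  }
})

test_that("translation pairs keep semantic identity source vs target", {
  rec <- fx_molecules(60, seed = 13)
  corp <- prepareCorpus(rec, seed = 5)
  vocab <- vocabulary(corp)
  for (i in seq_len(nrow(rec))) {
    src <- detokenizeSmiles(decodeTokens(vocab, corp@source_ids[[i]]))
    tgt <- detokenizeSmiles(decodeTokens(vocab, corp@target_ids[[i]]))
    expect_identical(canonicalizeSmiles(src), canonicalizeSmiles(tgt))
  }
})

test_that("smi files round-trip through readSmi/writeSmi", {
  rec <- fx_molecules(20, seed = 13)
  path <- withr::local_tempfile(fileext = ".smi")
  writeSmi(rec$canonical_smiles, path, ids = rec$id)
  back <- readSmi(path)
  expect_identical(back$smiles, rec$canonical_smiles)
  expect_identical(back$id, rec$id)
})

test_that("a prepared corpus is written as CSV plus JSON vocabulary", {
  rec <- fx_molecules(20, seed = 13)
  corp <- prepareCorpus(rec, seed = 3)
  dir <- withr::local_tempdir()
  writeCorpus(corp, dir)
  tab <- read.csv(file.path(dir, "corpus.csv"))
  expect_identical(names(tab), c("id", "canonical_smiles", "random_smiles",
                                 "n_heavy", "mw", "bucket"))
  expect_equal(nrow(tab), 20L)
  voc <- unlist(jsonlite::read_json(file.path(dir, "vocabulary.json")))
  expect_identical(voc, vocabTokens(vocabulary(corp)))
})
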