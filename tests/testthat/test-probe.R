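# Latent-representation probing: classifier metrics, split integrity,
# similarity groups, chemical-space embedding.

test_that("the Matthews correlation follows the confusion-table formula", {
  expect_equal(matthewsCorrelation(40, 40, 10, 10), 0.6)  # (1600-100)/2500
  expect_equal(matthewsCorrelation(50, 50, 0, 0), 1)
  expect_equal(matthewsCorrelation(0, 0, 50, 50), -1)
  expect_equal(matthewsCorrelation(10, 0, 0, 0), 0)       # empty marginal
})

test_that("a perfectly leaking descriptor yields AUROC 1", {
  set.seed(1)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- cbind(matrix(rnorm(n * 5), n), y)
  r <- runProbe(X, y, n_trials = 3L, seed = 2)
  expect_equal(r$auroc, 1)
  expect_equal(r$mcc, 1)
})

test_that("single-class labels are rejected and splits stay disjoint", {
  X <- matrix(rnorm(100), 20)
  expect_error(runProbe(X, rep(1L, 20)), "single class")
  set.seed(3)
  y <- rep(0:1, 50)
  X <- matrix(rnorm(100 * 4), 100)
  r <- runProbe(X, y, n_trials = 2L, seed = 5)
  expect_true(all(r$test_idx %in% 1:100))
  expect_equal(length(r$test_idx), 25L)
})

test_that("signal-free descriptors score at chance", {
  set.seed(7)
  n <- 2000
  X <- matrix(rnorm(n * 10), n)
  y <- sample(rep(0:1, n / 2))
  r <- runProbe(X, y, n_trials = 3L, seed = 11)
  expect_gte(r$auroc, 0.42)
  expect_lte(r$auroc, 0.58)
})

test_that("permutation null is centred on AUROC 0.5", {
  set.seed(19)
  n <- 400
  X <- matrix(rnorm(n * 8), n)
  y <- rep(0:1, n / 2)
  aucs <- vapply(1:20, function(k) {
    runProbe(X, sample(y), n_trials = 2L, seed = 100 + k)$auroc
  }, numeric(1))
  expect_gte(mean(aucs), 0.47)
  expect_lte(mean(aucs), 0.53)
})

test_that("similarity groups use a strict threshold and honor exclusions", {
  sm <- c("CCO", "CCN", "c1ccccc1O", "CCCO")
  fp <- ecfpFingerprints(sm)
  ref_sim <- suppressWarnings(
    tanimotoSimilarity(fp, matrix(fp[1, ], nrow(fp), ncol(fp), byrow = TRUE)))
  # reference is always a member of its own group (self-similarity 1)
  memb <- assignSimilarityGroups(sm, list(list(name = "g",
                                               reference = "CCO")))
  expect_true(memb[1, "g"])
  # a molecule at exactly the threshold is NOT a member (strict inequality)
  thr <- ref_sim[4]
  m2 <- assignSimilarityGroups(sm, list(list(name = "g", reference = "CCO",
                                             threshold = thr)))
  expect_false(m2[4, "g"])
  m3 <- assignSimilarityGroups(sm, list(list(name = "g", reference = "CCO",
                                             threshold = thr - 1e-9)))
  expect_true(m3[4, "g"])
  # exclusion removes an otherwise similar molecule
  m4 <- assignSimilarityGroups(sm, list(list(name = "g", reference = "CCO",
                                             exclude = "CCO")))
  expect_false(m4[1, "g"])
  expect_error(assignSimilarityGroups(sm, list(list(name = "g",
                                                    reference = "C(("))),
               "unparseable")
})

test_that("raising the threshold never adds group members", {
  rec <- fx_molecules(60, seed = 13)
  sm <- rec$canonical_smiles
  lo <- assignSimilarityGroups(sm, list(list(name = "g", reference = sm[1],
                                             threshold = 0.2)))
  hi <- assignSimilarityGroups(sm, list(list(name = "g", reference = sm[1],
                                             threshold = 0.4)))
  expect_true(all(lo[hi[, "g"], "g"]))           # hi members subset lo members
  expect_lte(sum(hi), sum(lo))
})

test_that("trained descriptors group similar structures in the embedding", {
  tr <- fx_trend()
  best <- which.max(checkpointAccuracy(tr$checkpoints))
  refs <- list(list(name = "phenols", reference = "Oc1ccccc1"),
               list(name = "cyclohexanols", reference = "OC1CCCCC1"),
               list(name = "acids", reference = "CCCC(=O)O"))
  memb <- assignSimilarityGroups(tr$eval$canonical_smiles, refs)
  z <- encodeMolecules(checkpointModels(tr$checkpoints)[[best]],
                       tr$eval$canonical_smiles)
  emb <- embedChemicalSpace(z, membership = memb, seed = 9)
  xy <- as.matrix(emb[, c("x", "y")])
  d <- as.matrix(dist(xy))
  gid <- apply(memb, 1, function(r) if (any(r)) which(r)[1] else NA)
  ing <- which(!is.na(gid))
  sil <- vapply(ing, function(i) {
    own <- setdiff(ing[gid[ing] == gid[i]], i)
    oth <- ing[gid[ing] != gid[i]]
    if (!length(own) || !length(oth)) return(NA_real_)
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0)
})

test_that("chemical-space embedding is seeded and shape-preserving", {
  set.seed(23)
  X <- matrix(rnorm(60 * 8), 60)
  e1 <- embedChemicalSpace(X, seed = 4)
  e2 <- embedChemicalSpace(X, seed = 4)
  expect_equal(nrow(e1), 60L)
  expect_identical(e1, e2)
  expect_error(embedChemicalSpace(X[1:5, ], seed = 1), "at least 10")
  memb <- matrix(rep(c(TRUE, FALSE), 30), ncol = 1,
                 dimnames = list(NULL, "grp"))
  e3 <- embedChemicalSpace(X, membership = memb, seed = 4)
  expect_true("grp" %in% names(e3))
  expect_s3_class(plotChemicalSpace(e3, "grp"), "ggplot")
})
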