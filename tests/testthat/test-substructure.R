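# Fingerprint Tanimoto agreement between inputs and decoded structures.

test_that("tanimoto similarity matches the set formula", {
  expect_equal(tanimotoSimilarity(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimotoSimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # |a^b| = 2, |a| = 3, |b| = 4 -> 2 / (3 + 4 - 2) = 0.4
  a <- c(1, 1, 1, 0, 0, 0)
  b <- c(1, 1, 0, 1, 1, 0)
  expect_equal(tanimotoSimilarity(a, b), 0.4)
  expect_equal(tanimotoSimilarity(b, a), 0.4)     # symmetric
  expect_error(tanimotoSimilarity(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_warning(z <- tanimotoSimilarity(numeric(3), numeric(3)), "empty")
  expect_equal(z, 1)
})

test_that("row-wise matrix tanimoto agrees with the naive per-pair oracle", {
  set.seed(5)
  A <- matrix(rbinom(200, 1, 0.3), 10)
  B <- matrix(rbinom(200, 1, 0.3), 10)
  got <- suppressWarnings(tanimotoSimilarity(A, B))
  want <- vapply(1:10, function(i) oracle_tanimoto(A[i, ], B[i, ]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fingerprints have the documented widths and self-similarity 1", {
  sm <- c("CCO", "CCN", "c1ccccc1O")
  m <- maccsFingerprints(sm)
  e <- ecfpFingerprints(sm)
  expect_equal(dim(m), c(3L, 166L))
  expect_equal(dim(e), c(3L, 2048L))
  expect_equal(unname(tanimotoSimilarity(m, m)), rep(1, 3))
  expect_equal(unname(tanimotoSimilarity(e, e)), rep(1, 3))
})

test_that("ethanol/ethylamine MACCS agreement equals the brute-force count", {
  fp <- maccsFingerprints(c("CCO", "CCN"))
  want <- oracle_tanimoto(fp[1, ], fp[2, ])
  expect_equal(tanimotoSimilarity(fp[1, ], fp[2, ]), want, tolerance = 1e-12)
  expect_lt(want, 1)
  expect_gt(want, 0)
})

test_that("common-valid selection applies the universal-quantifier rule", {
  tr <- list(
    data.frame(input = c("a", "b", "c"),
               predicted = c("CCO", "CCN", "CCC")),
    data.frame(input = c("a", "b", "c"),
               predicted = c("CCO", "C((", "CCC")),
    data.frame(input = c("a", "b", "c"),
               predicted = c("xx[", "zz", "qq")))
  acc <- c(0.9, 0.5, 0.0005)
  sel <- selectCommonValid(tr, acc, min_accuracy_threshold = 0.001)
  expect_equal(sel$qualifying, c(1L, 2L))    # Model_0.05 does not qualify
  expect_equal(sel$subset, c(1L, 3L))        # "C((" invalid under ckpt 2
  sel_all <- selectCommonValid(tr[1], 0.9)
  expect_equal(sel_all$subset, 1:3)          # all valid -> full set
  expect_error(selectCommonValid(tr, acc, min_accuracy_threshold = 0.95),
               "threshold")
})

test_that("exact translations give mean Tanimoto 1 for both fingerprints", {
  inputs <- c("CCO", "c1ccccc1O", "CC(=O)O")
  tr <- list(data.frame(input = inputs, predicted = inputs))
  agg <- agreementByCheckpoint(tr, inputs, subset = 1:3,
                               checkpoint_names = "Model_100")
  expect_equal(agg$summary$maccs_mean, 1)
  expect_equal(agg$summary$ecfp_mean, 1)
  expect_equal(agg$summary$n, 3L)
})
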