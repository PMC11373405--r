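test_that("score matrix matches the explicit bilinear form", {
  set.seed(3)
  d <- 8; r <- 2
  model <- makeScoringModel(d, r, seed = 1)
  embS <- matrix(rnorm(5 * d), 5, d)
  embT <- matrix(rnorm(7 * d), 7, d)
  A <- scoreMatrix(embS, embT, model)
  # brute force with the full W = R R^T, entry by entry
  W <- model@R %*% t(model@R)
  ref <- matrix(0, 5, 7)
  for (i in 1:5) for (j in 1:7)
    ref[i, j] <- 1 / (1 + exp(-drop(embS[i, ] %*% W %*% embT[j, ])))
  expect_equal(A, ref, tolerance = 1e-12)
  # bilinear symmetry
  expect_equal(A, t(scoreMatrix(embT, embS, model)), tolerance = 1e-12)
  # zero factor gives the indifferent 0.5 everywhere
  z <- makeScoringModel(d, r, R = matrix(0, d, r))
  expect_true(all(scoreMatrix(embS, embT, z) == 0.5))
  expect_error(scoreMatrix(embS[, 1:3], embT, model), "dimension")
})

test_that("compression is consistent with scoring and shape-correct", {
  set.seed(5)
  d <- 8L; r <- 3L
  model <- makeScoringModel(d, r, seed = 2)
  emb <- matrix(rnorm(6 * d), 6, d)
  cz <- compressEmbeddings(emb, model)
  expect_identical(dim(cz), c(6L, r))
  # identity factor (square R is rejected, so check on the math directly)
  embT <- matrix(rnorm(4 * d), 4, d)
  A <- scoreMatrix(emb, embT, model)
  expect_identical(A, 1 / (1 + exp(-tcrossprod(cz, compressEmbeddings(embT, model)))))
  expect_identical(nrow(compressEmbeddings(emb[0, , drop = FALSE], model)), 0L)
  # self-score diagonal is sigmoid of a PSD quadratic form: always >= 0.5
  expect_true(all(diag(scoreMatrix(emb, emb, model)) >= 0.5))
})

test_that("pair target matrices place ones at aligned coordinates", {
  ident <- cbind(0:2, 0:2)
  expect_identical(pairTargetMatrix(ident, 3, 3), diag(3))
  expect_identical(pairTargetMatrix(matrix(0L, 0, 2), 2, 4), matrix(0, 2, 4))
  msa <- ProfileMSA(c("r1", "r2"), c("AC-E", "A-DE"))
  pa <- inducePairwiseAlignments(msa)[[1]]
  tm <- pairTargetMatrix(pa, 3, 3)
  expect_identical(which(tm == 1), c(1L, 9L))  # (0,0) and (2,2) 0-based
  expect_error(pairTargetMatrix(cbind(5L, 0L), 3, 3), "out of range")
})

test_that("binary cross-entropy matches hand computation", {
  A <- matrix(0.5, 3, 3)
  expect_equal(bceLoss(A, diag(3)), log(2), tolerance = 1e-12)
  # near-perfect prediction
  perfect <- diag(3) * 0.9999999 + (1 - diag(3)) * 1e-7
  expect_lt(bceLoss(perfect, diag(3)), 1e-5)
  A2 <- matrix(c(0.9, 0.2, 0.3, 0.8), 2, 2)
  t2 <- matrix(c(1, 0, 0, 1), 2, 2)
  hand <- -(2 * log(0.9) + log(1 - 0.2) + log(1 - 0.3) + 2 * log(0.8)) / 4
  expect_equal(bceLoss(A2, t2, posWeight = 2), hand, tolerance = 1e-10)
  # exact 0/1 scores are clamped, not infinite
  expect_true(is.finite(bceLoss(matrix(c(0, 1), 1, 2), matrix(c(0, 1), 1, 2))))
})

test_that("parameter count is the low-rank factor size", {
  expect_identical(parameterCount(makeScoringModel(1024, 16)), 16384L)
  expect_identical(parameterCount(makeScoringModel(2, 1)), 2L)
  expect_identical(parameterCount(makeScoringModel(8, 2)), 16L)
})

test_that("pretraining learns planted residue-pair signal", {
  d <- 32; L <- 10
  train <- makePlantedPairs(40, L = L, d = d, latentDim = 12, noise = 0.5,
                            seed = 71)
  held <- makePlantedPairs(10, L = L, d = d, latentDim = 12, noise = 0.5,
                           seed = 72)
  model <- pretrainScoringModel(train, r = 16, epochs = 40, seed = 3)
  trace <- attr(model, "lossTrace")
  expect_true(all(diff(trace) < 1e-3))  # non-increasing within tolerance
  scores <- labels <- c()
  for (p in held) {
    A <- scoreMatrix(p$embS, p$embT, model)
    tmat <- pairTargetMatrix(p$pairs, L, L)
    scores <- c(scores, as.vector(A)); labels <- c(labels, as.vector(tmat))
  }
  expect_gte(aurocOf(scores, labels), 0.9)
  # epochs = 0 returns the seeded initialization unchanged
  init <- pretrainScoringModel(train, r = 16, epochs = 0, seed = 3)
  expect_identical(init@R, makeScoringModel(d, 16, seed = 3)@R)
  # determinism
  again <- pretrainScoringModel(train, r = 16, epochs = 40, seed = 3)
  expect_identical(model@R, again@R)
  expect_error(pretrainScoringModel(train, r = d), "low-rank")
})

test_that("scoring model serialization round-trips", {
  model <- makeScoringModel(12, 3, seed = 9)
  f <- tempfile(fileext = ".json")
  writeScoringModel(model, f)
  back <- readScoringModel(f)
  expect_equal(back@R, model@R, tolerance = 0)
  expect_identical(back@activation, "logistic-sigmoid")
  expect_error(makeScoringModel(4, 4), "low-rank")
})
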