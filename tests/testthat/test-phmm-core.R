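test_that("forward equals the brute-force path sum on small models", {
  set.seed(7)
  for (t in 1:40) {
    hmm <- randomToyHMM(sample(1:3, 1), seed = 100 + t)
    L <- sample(1:4, 1)
    seq <- paste(sample(c("A", "C", "D", "X"), L, replace = TRUE),
                 collapse = "")
    extra <- NULL
    if (t %% 3 == 0) {
      extra <- list(match = list(matrix(rnorm(nMatch(hmm) * L, sd = 0.5),
                                        nMatch(hmm), L)),
                    insert = list(rnorm(L, sd = 0.5)))
    }
    ps <- oraclePathProbs(hmm, seq, extra)
    expect_equal(unname(forwardLogLik(hmm, setNames(seq, "s"), extra)),
                 log(sum(ps)), tolerance = 1e-10)
  }
})

test_that("an all-zero extra emission term leaves the likelihood unchanged", {
  hmm <- randomToyHMM(3, seed = 5)
  seqs <- setNames(c("ACD", "CADA"), c("a", "b"))
  batch <- encodeSequences(seqs, hmm@alphabet)
  zero <- list(match = lapply(batch@lengths, function(L) matrix(0, 3, L)),
               insert = lapply(batch@lengths, function(L) rep(0, L)))
  expect_identical(forwardLogLik(hmm, batch, zero),
                   forwardLogLik(hmm, batch))
})

test_that("a deterministic single-path model assigns probability one", {
  # begin -> body -> M1 -> M2 -> end, emissions forced
  lg <- function(p) log(pmax(p, 1e-300))
  big <- 300  # logit gap making the softmax effectively one-hot
  tl <- list(begin = c(-big, 0), flankL = c(-big, 0), entry = c(0, -big),
             match = matrix(c(0, -big, -big), 1, 3),
             insert = matrix(c(0, 0), 1, 2),
             delete = matrix(c(0, 0), 1, 2),
             exit = c(-big, 0), flankR = c(-big, 0))
  ml <- matrix(-big, 2, 3); ml[1, 1] <- 0; ml[2, 2] <- 0  # emits "AC"
  hmm <- makeProfileHMM(2, alphabet = c("A", "C", "D"), matchLogits = ml,
                        insertLogits = rep(0, 3), transLogits = tl)
  ll <- forwardLogLik(hmm, setNames("AC", "s"))
  expect_equal(unname(ll), 0, tolerance = 1e-9)
  vit <- viterbiDecode(hmm, "AC")
  expect_equal(vit$logProb, unname(ll), tolerance = 1e-9)
  expect_identical(vit$path$state, c("M", "M"))
})

test_that("viterbi equals the brute-force path max and never exceeds forward", {
  set.seed(11)
  for (t in 1:40) {
    hmm <- randomToyHMM(sample(1:3, 1), seed = 300 + t)
    L <- sample(1:4, 1)
    seq <- paste(sample(c("A", "C", "D"), L, replace = TRUE), collapse = "")
    ps <- oraclePathProbs(hmm, seq)
    vit <- viterbiDecode(hmm, seq)
    expect_equal(vit$logProb, log(max(ps)), tolerance = 1e-10)
    expect_lte(vit$logProb,
               unname(forwardLogLik(hmm, setNames(seq, "s"))) + 1e-12)
  }
})

test_that("viterbi ties prefer match over delete, deterministically", {
  # one residue against a two-state profile: the paths {M1 emit, D2} and
  # {D1, M2 emit} are exactly tied (all three factors of each path equal
  # 0.5 in floating point). The tie rule applies at each decoding
  # decision; at the final body state Match beats Delete, so the path
  # running through M2 wins.
  a <- log(0.5)
  tl <- list(begin = c(-300, 0), flankL = c(0, 0), entry = c(0, 0),
             match = matrix(c(a, a, 0), 1, 3), insert = matrix(0, 1, 2),
             delete = matrix(0, 1, 2), exit = c(-300, 0), flankR = c(0, 0))
  hmm <- makeProfileHMM(2, alphabet = c("A", "C"),
                        matchLogits = matrix(0, 2, 2),
                        insertLogits = c(0, 0), transLogits = tl)
  tp <- transitionProbs(hmm)
  # precondition: the two paths are exactly tied (flank detours through the
  # near-zero begin->flank probability also exist but are ~1e-131)
  expect_identical(unname(tp$match[1, "toD"]), unname(tp$delete[1, "toM"]))
  ps <- sort(oraclePathProbs(hmm, "A"), decreasing = TRUE)
  expect_identical(unname(ps[1]), unname(ps[2]))
  expect_lt(ps[3] / ps[1], 1e-100)
  vit <- viterbiDecode(hmm, "A")
  expect_identical(vit$path$state, c("D", "M"))
  expect_identical(vit$path$index, c(1L, 2L))
  expect_equal(vit$logProb, 3 * a, tolerance = 1e-12)
  # and decoding is deterministic
  expect_identical(viterbiDecode(hmm, "A"), vit)
})

test_that("total probability over all short sequences approaches one", {
  # a proper end state makes the model a distribution over sequences: on a
  # 2-letter alphabet, summing exp(loglik) over all sequences up to length
  # 12 must approach 1 when long sequences are improbable
  lg <- log
  tl <- list(begin = lg(c(0.1, 0.9)), flankL = lg(c(0.2, 0.8)),
             entry = lg(c(0.9, 0.1)),
             match = matrix(rep(lg(c(0.8, 0.1, 0.1)), each = 1), 1, 3),
             insert = matrix(lg(c(0.7, 0.3)), 1, 2),
             delete = matrix(lg(c(0.8, 0.2)), 1, 2),
             exit = lg(c(0.1, 0.9)), flankR = lg(c(0.2, 0.8)))
  set.seed(3)
  hmm <- makeProfileHMM(2, alphabet = c("A", "C"),
                        matchLogits = matrix(rnorm(4), 2, 2),
                        insertLogits = c(0, 0), transLogits = tl)
  # the empty sequence (all-delete path, no flank emissions) is part of the
  # model's support; add its probability in closed form
  tp <- transitionProbs(hmm)
  total <- tp$begin[["body"]] * tp$entry[["D1"]] * tp$delete[1, "toD"] *
    tp$exit[["end"]]
  for (L in 1:12) {
    seqs <- do.call(expand.grid, rep(list(c("A", "C")), L))
    strs <- apply(as.matrix(seqs), 1, paste, collapse = "")
    names(strs) <- paste0("s", seq_along(strs))
    total <- total + sum(exp(forwardLogLik(hmm, strs)))
  }
  expect_gte(total, 0.999)
  expect_lte(total, 1 + 1e-9)
})

test_that("viterbi <= forward over many random model/sequence pairs", {
  set.seed(19)
  for (t in 1:200) {
    hmm <- randomToyHMM(sample(1:4, 1), seed = 5000 + t)
    L <- sample(1:6, 1)
    seq <- paste(sample(c("A", "C", "D"), L, replace = TRUE), collapse = "")
    vit <- viterbiDecode(hmm, seq)
    expect_lte(vit$logProb,
               unname(forwardLogLik(hmm, setNames(seq, "s"))) + 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  hmm <- randomToyHMM(3, seed = 23)
  batch <- encodeSequences(setNames(c("ACD", "CDA", "AACD"), paste0("s", 1:3)),
                           hmm@alphabet)
  gr <- dpHMM:::forwardBackwardGrad(hmm, batch)
  fdGrad <- function(getter, setter, eps = 1e-5) {
    p0 <- getter(hmm)
    g <- p0 * 0
    for (k in seq_along(p0)) {
      for (sgn in c(1, -1)) {
        p <- p0; p[k] <- p[k] + sgn * eps
        g[k] <- g[k] + sgn * sum(forwardLogLik(setter(hmm, p), batch)) /
          (2 * eps)
      }
    }
    g
  }
  gm <- fdGrad(function(h) h@matchLogits,
               function(h, p) { h@matchLogits <- p; h })
  expect_equal(unname(gm), unname(gr$gMatchLogits), tolerance = 1e-4)
  gi <- fdGrad(function(h) h@insertLogits,
               function(h, p) { h@insertLogits <- p; h })
  expect_equal(unname(gi), unname(gr$gInsertLogits), tolerance = 1e-4)
  for (nm in names(hmm@transLogits)) {
    gt <- fdGrad(function(h) h@transLogits[[nm]],
                 function(h, p) { h@transLogits[[nm]] <- p; h })
    expect_equal(unname(gt), unname(gr$gTransLogits[[nm]]), tolerance = 1e-4,
                 info = nm)
  }
})

test_that("input validation rejects bad models and sequences", {
  hmm <- randomToyHMM(2, seed = 2)
  expect_error(encodeSequences(setNames("", "s")), "empty")
  bad <- hmm
  bad@matchLogits[1, 1] <- NaN
  expect_error(forwardLogLik(bad, setNames("AC", "s")), "finite")
  b <- encodeSequences(setNames("AC", "s"), hmm@alphabet)
  expect_error(forwardLogLik(hmm, b,
                             list(match = list(matrix(NA_real_, 2, 2)))),
               "finite|nMatch")
})

test_that("amino Dirichlet-mixture prior density matches direct computation", {
  # uniform Dirichlet (alpha = 1): density is the constant log Gamma(20)
  hmm <- makeProfileHMM(3, seed = 4)
  flat <- list(weights = 1, alpha = matrix(1, 1, 20))
  expect_equal(aminoPriorLogDensity(hmm, flat), 3 * lgamma(20),
               tolerance = 1e-9)
  # two-component mixture vs an independently coded density
  set.seed(6)
  z <- rnorm(20)
  p <- exp(z) / sum(exp(z))
  prior <- list(weights = c(0.3, 0.7),
                alpha = rbind(runif(20, 0.5, 2), runif(20, 0.5, 2)))
  direct <- log(sum(sapply(1:2, function(m) {
    a <- prior$alpha[m, ]
    prior$weights[m] * exp(lgamma(sum(a)) - sum(lgamma(a)) +
                             sum((a - 1) * log(p)))
  })))
  expect_equal(aminoPriorLogDensity(matrix(p, 1), prior), direct,
               tolerance = 1e-9)
  # zero match states contribute nothing
  expect_equal(aminoPriorLogDensity(matrix(0, 0, 20), prior), 0)
  expect_error(aminoPriorLogDensity(matrix(2 * p, 1), prior), "simplex")
})

test_that("profile serialization round-trips bit-identically", {
  hmm <- randomToyHMM(3, seed = 31)
  f <- tempfile(fileext = ".json")
  writeProfileHMM(hmm, f)
  back <- readProfileHMM(f)
  expect_identical(back@nMatch, hmm@nMatch)
  expect_identical(back@alphabet, hmm@alphabet)
  expect_equal(back@matchLogits, hmm@matchLogits, tolerance = 0)
  expect_equal(back@transLogits, hmm@transLogits, tolerance = 0)
  expect_identical(forwardLogLik(back, setNames("ACDA", "s")),
                   forwardLogLik(hmm, setNames("ACDA", "s")))
})
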