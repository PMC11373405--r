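test_that("diagonal Gaussian log-density matches closed forms and dnorm", {
  r <- 16
  expect_equal(gaussianLogDensity(rep(0, r), rep(0, r), rep(1, r)),
               -8 * log(2 * pi), tolerance = 1e-12)
  expect_equal(gaussianLogDensity(1, 0, 1), -0.5 * (log(2 * pi) + 1),
               tolerance = 1e-12)
  set.seed(41)
  x <- rnorm(5); m <- rnorm(5); v <- runif(5, 0.5, 2)
  expect_equal(gaussianLogDensity(x, m, v),
               sum(dnorm(x, m, sqrt(v), log = TRUE)), tolerance = 1e-12)
  expect_error(gaussianLogDensity(x, m[1:3], v), "mismatch")
})

test_that("the 1-D unit Gaussian density integrates to one", {
  dens <- Vectorize(function(x) exp(gaussianLogDensity(x, 0, 1)))
  q <- integrate(dens, -10, 10, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("the tempered joint emission scales the embedding term", {
  expect_identical(jointEmissionLogProb(-2.5, -7, 0), -2.5)
  expect_identical(jointEmissionLogProb(-2.5, -7, 1), -9.5)
  expect_identical(jointEmissionLogProb(0, -3, 0.5), -1.5)
  expect_error(jointEmissionLogProb(-1, -1, -0.1), "non-negative")
})

test_that("the emission grid composes densities with the temperature", {
  set.seed(13)
  LM <- 4L; r <- 3L; L <- 6L
  ems <- makeEmbeddingEmissions(matrix(rnorm(LM * r), LM, r),
                                matrix(runif(LM * r, 0.5, 2), LM, r),
                                tau = 0.7)
  comp <- matrix(rnorm(L * r), L, r)
  g <- embeddingEmissionGrid(ems, comp)
  expect_identical(dim(g$match), c(LM, L))
  # loop-based reference
  vars <- embeddingVars(ems)
  ref <- matrix(0, LM, L)
  for (i in 1:LM) for (j in 1:L)
    ref[i, j] <- 0.7 * gaussianLogDensity(comp[j, ], ems@mean[i, ],
                                          vars[i, ])
  expect_equal(g$match, ref, tolerance = 1e-10)
  bgRef <- sapply(1:L, function(j)
    0.7 * gaussianLogDensity(comp[j, ], ems@bgMean, ems@bgVar))
  expect_equal(g$insert, bgRef, tolerance = 1e-10)
  # tau = 0 switches embeddings off entirely
  ems0 <- makeEmbeddingEmissions(ems@mean, vars, tau = 0)
  g0 <- embeddingEmissionGrid(ems0, comp)
  expect_true(all(g0$match == 0) && all(g0$insert == 0))
  # single state, single position reduces to one density
  ems1 <- makeEmbeddingEmissions(matrix(0, 1, r), matrix(1, 1, r), tau = 1)
  g1 <- embeddingEmissionGrid(ems1, comp[1, , drop = FALSE])
  expect_equal(g1$match[1, 1],
               gaussianLogDensity(comp[1, ], rep(0, r), rep(1, r)),
               tolerance = 1e-10)
  expect_error(embeddingEmissionGrid(ems, comp[, 1:2]), "dimension")
})

test_that("the mixture prior density reduces, peaks and permutes correctly", {
  set.seed(17)
  r <- 4
  prior <- new("EmbeddingPrior", weights = c(0.6, 0.4),
               mean = matrix(c(rep(10, r), rep(-10, r)), 2, r, byrow = TRUE),
               var = matrix(0.01, 2, r))
  ems <- makeEmbeddingEmissions(matrix(rep(10, r), 1, r),
                                matrix(1, 1, r), tau = 1)
  # mean at the heaviest, well-separated component: density ~ log w + peak
  peak <- gaussianLogDensity(rep(10, r), rep(10, r), rep(0.01, r))
  expect_equal(priorLogDensity(ems, prior), log(0.6) + peak,
               tolerance = 1e-6)
  # C = 1 reduces to a plain Gaussian
  p1 <- new("EmbeddingPrior", weights = 1, mean = matrix(rnorm(r), 1),
            var = matrix(runif(r, 0.5, 1), 1))
  mu <- matrix(rnorm(3 * r), 3, r)
  emsM <- makeEmbeddingEmissions(mu, matrix(1, 3, r), tau = 1)
  direct <- sum(sapply(1:3, function(i)
    gaussianLogDensity(mu[i, ], p1@mean[1, ], p1@var[1, ])))
  expect_equal(priorLogDensity(emsM, p1), direct, tolerance = 1e-10)
  # zero match states
  ems0 <- makeEmbeddingEmissions(matrix(0, 0, r), matrix(1, 0, r), tau = 1)
  expect_identical(priorLogDensity(ems0, p1), 0)
  # permutation invariance over components
  set.seed(23)
  p3 <- new("EmbeddingPrior", weights = c(0.2, 0.5, 0.3),
            mean = matrix(rnorm(3 * r), 3, r),
            var = matrix(runif(3 * r, 0.2, 2), 3, r))
  perm <- c(3, 1, 2)
  p3p <- new("EmbeddingPrior", weights = p3@weights[perm],
             mean = p3@mean[perm, ], var = p3@var[perm, ])
  expect_equal(priorLogDensity(emsM, p3), priorLogDensity(emsM, p3p),
               tolerance = 1e-12)
})

test_that("EM recovers a planted two-component mixture", {
  set.seed(29)
  r <- 3; N <- 600
  muA <- rep(2, r); muB <- rep(-2, r)
  x <- rbind(matrix(rnorm(N / 2 * r, mean = 2, sd = 0.5), N / 2, r),
             matrix(rnorm(N / 2 * r, mean = -2, sd = 0.5), N / 2, r))
  prior <- fitEmbeddingPrior(x, C = 2, seed = 9)
  trace <- attr(prior, "logLikTrace")
  expect_true(all(diff(trace) > -1e-6))
  # match recovered components to the planted means
  d1 <- sqrt(sum((prior@mean[1, ] - muA)^2))
  ord <- if (d1 < sqrt(sum((prior@mean[1, ] - muB)^2))) 1:2 else 2:1
  expect_lt(max(abs(prior@mean[ord[1], ] - muA)), 0.1)
  expect_lt(max(abs(prior@mean[ord[2], ] - muB)), 0.1)
  expect_equal(prior@weights[order(prior@weights)], c(0.5, 0.5),
               tolerance = 0.05)
  # determinism under the seed
  again <- fitEmbeddingPrior(x, C = 2, seed = 9)
  expect_identical(prior@mean, again@mean)
})

test_that("EM closed form at C = 1 and variance clamping on degenerate input", {
  set.seed(37)
  x <- matrix(rnorm(50 * 2), 50, 2)
  p <- fitEmbeddingPrior(x, C = 1, seed = 1)
  expect_equal(as.vector(p@mean), colMeans(x), tolerance = 1e-8)
  expect_equal(as.vector(p@var),
               apply(x, 2, function(col) mean((col - mean(col))^2)),
               tolerance = 1e-8)
  ident <- matrix(1, 20, 3)
  pd <- fitEmbeddingPrior(ident, C = 2, seed = 1)
  expect_true(all(pd@var == dpHMM:::VAR_FLOOR))
  expect_error(fitEmbeddingPrior(x, C = 0), "C must be")
})

test_that("embedding prior serialization round-trips", {
  set.seed(53)
  prior <- fitEmbeddingPrior(matrix(rnorm(200), 50, 4), C = 2, seed = 3)
  f <- tempfile(fileext = ".json")
  writeEmbeddingPrior(prior, f)
  back <- readEmbeddingPrior(f)
  expect_equal(back@weights, prior@weights, tolerance = 0)
  expect_equal(back@mean, prior@mean, tolerance = 0)
  expect_equal(back@var, prior@var, tolerance = 0)
})

test_that("initialization from the prior is deterministic and unbiased", {
  set.seed(43)
  r <- 3
  prior <- new("EmbeddingPrior", weights = c(0.3, 0.7),
               mean = matrix(rnorm(2 * r), 2, r),
               var = matrix(runif(2 * r, 0.1, 0.5), 2, r))
  e1 <- initEmissionsFromPrior(prior, 6, seed = 5)
  e2 <- initEmissionsFromPrior(prior, 6, seed = 5)
  expect_identical(e1@mean, e2@mean)
  expect_identical(e1@scaleRaw, e2@scaleRaw)
  # law of large numbers: empirical mean over many sampled states
  big <- initEmissionsFromPrior(prior, 10000, seed = 7)
  mixMean <- as.vector(t(prior@mean) %*% prior@weights)
  mm <- dpHMM:::momentMatchPrior(prior)
  se <- sqrt(mm$var / 10000)
  expect_true(all(abs(colMeans(big@mean) - mixMean) < 3 * se))
  # a zero-variance-floored single component pins all means
  p0 <- new("EmbeddingPrior", weights = 1,
            mean = matrix(2, 1, r), var = matrix(dpHMM:::VAR_FLOOR, 1, r))
  e0 <- initEmissionsFromPrior(p0, 5, seed = 1)
  expect_equal(e0@mean, matrix(2, 5, r), tolerance = 1e-2)
})
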