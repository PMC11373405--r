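## Embedding emissions: diagonal Gaussians at match states, the tempered
## joint emission, the mixture-of-Gaussians prior over match means, and
## the EM fitter for that prior.

#' Log-density of a diagonal multivariate normal
#'
#' `-1/2 * sum_k [ log(2 pi var_k) + (x_k - mean_k)^2 / var_k ]`.
#'
#' @param x,mean numeric vectors of equal length.
#' @param var positive variances (diagonal covariance), same length.
#' @return scalar log-density.
#' @export
gaussianLogDensity <- function(x, mean, var) {
  if (length(x) != length(mean) || length(x) != length(var))
    stop("dimension mismatch between x, mean and var")
  if (any(var < VAR_FLOOR)) stop("variances below the variance floor")
  -0.5 * sum(log(2 * pi * var) + (x - mean)^2 / var)
}

#' Tempered joint emission log-probability
#'
#' The joint emission of a residue and its embedding at a state is
#' `P(residue | q) * P(embedding | q)^tau`; in log space the temperature
#' simply scales the embedding term.
#'
#' @param aaLogProb residue emission log-probability.
#' @param embLogDensity embedding emission log-density.
#' @param tau non-negative temperature.
#' @return `aaLogProb + tau * embLogDensity`.
#' @export
jointEmissionLogProb <- function(aaLogProb, embLogDensity, tau) {
  if (tau < 0) stop("tau must be non-negative")
  stopIfNotFinite(c(aaLogProb, embLogDensity), "emission terms")
  aaLogProb + tau * embLogDensity
}

#' Construct an embedding emission model
#'
#' @param mean `nMatch x r` Gaussian means.
#' @param var `nMatch x r` variances (floored at the variance floor and
#'   stored via the softplus parameterization).
#' @param tau temperature (default 1).
#' @param bgMean,bgVar background Gaussian for insert/flank states; by
#'   default standard normal. [momentMatchPrior()] derives these from an
#'   embedding prior.
#' @return an [EmbeddingEmissions-class].
#' @export
makeEmbeddingEmissions <- function(mean, var, tau = 1,
                                   bgMean = NULL, bgVar = NULL) {
  mean <- as.matrix(mean); var <- as.matrix(var)
  r <- ncol(mean)
  if (is.null(bgMean)) bgMean <- rep(0, r)
  if (is.null(bgVar)) bgVar <- rep(1, r)
  new("EmbeddingEmissions", mean = mean,
      scaleRaw = softplusInv(pmax(var, VAR_FLOOR) - VAR_FLOOR),
      tau = as.numeric(tau), bgMean = bgMean, bgVar = pmax(bgVar, VAR_FLOOR))
}

## log N(x_j; mu_i, var_i) for all states i and rows x_j: LM x L matrix
gaussianLogDensityGrid <- function(mean, var, x) {
  LM <- nrow(mean); L <- nrow(x)
  const <- -0.5 * rowSums(log(2 * pi * var))          # per state
  xv <- x^2
  ## quadratic form expanded: sum_k (x^2 - 2 x mu + mu^2) / var
  q <- xv %*% t(1 / var) - 2 * (x %*% t(mean / var)) +
    matrix(rowSums(mean^2 / var), L, LM, byrow = TRUE)
  const - 0.5 * t(q)   # LM x L
}

#' Per-state, per-position embedding emission terms
#'
#' Builds the extra emission term consumed by [forwardLogLik()] and
#' [viterbiDecode()]: entry `(i, j)` is `tau` times the Gaussian
#' log-density of the compressed embedding of residue `j` under match
#' state `i`. The accompanying `insert` component carries the frozen
#' background Gaussian log-density (times `tau`) used by insert and flank
#' states.
#'
#' @param ems an [EmbeddingEmissions-class].
#' @param compressed `L x r` matrix of compressed embeddings for one
#'   sequence.
#' @return list with `match` (`nMatch x L` matrix) and `insert`
#'   (length-`L` vector).
#' @export
embeddingEmissionGrid <- function(ems, compressed) {
  compressed <- as.matrix(compressed)
  if (ncol(compressed) != ncol(ems@mean))
    stop("compressed embedding dimension does not match the model")
  tau <- ems@tau
  if (tau == 0) {
    return(list(match = matrix(0, nrow(ems@mean), nrow(compressed)),
                insert = rep(0, nrow(compressed))))
  }
  vars <- embeddingVars(ems)
  grid <- tau * gaussianLogDensityGrid(ems@mean, vars, compressed)
  bg <- tau * gaussianLogDensityGrid(matrix(ems@bgMean, 1L),
                                     matrix(ems@bgVar, 1L), compressed)[1L, ]
  list(match = grid, insert = bg)
}

#' Log-density of match means under the embedding prior
#'
#' `sum_i log sum_c pi_c N(mu_i; mu_c, sigma_c)`, computed with
#' log-sum-exp.
#'
#' @param ems an [EmbeddingEmissions-class] (its means are evaluated).
#' @param prior an [EmbeddingPrior-class].
#' @return scalar log-density; 0 for zero match states.
#' @export
priorLogDensity <- function(ems, prior) {
  mu <- if (is(ems, "EmbeddingEmissions")) ems@mean else as.matrix(ems)
  if (nrow(mu) == 0L) return(0)
  comp <- componentLogDensities(mu, prior)
  sum(rowLogSumExp(comp))
}

## log(pi_c) + log N(mu_i; mu_c, var_c): nStates x C matrix
componentLogDensities <- function(mu, prior) {
  C <- length(prior@weights)
  out <- matrix(0, nrow(mu), C)
  for (c in seq_len(C)) {
    out[, c] <- log(prior@weights[c]) +
      gaussianLogDensityGrid(prior@mean[c, , drop = FALSE],
                             prior@var[c, , drop = FALSE], mu)[1L, ]
  }
  out
}

## gradient of priorLogDensity w.r.t. the match means
priorGradMeans <- function(ems, prior) {
  mu <- ems@mean
  if (nrow(mu) == 0L) return(mu)
  comp <- componentLogDensities(mu, prior)
  resp <- exp(comp - rowLogSumExp(comp))       # nStates x C
  grad <- matrix(0, nrow(mu), ncol(mu))
  for (c in seq_len(ncol(resp))) {
    grad <- grad + resp[, c] *
      sweep(-sweep(mu, 2L, prior@mean[c, ]), 2L, prior@var[c, ], "/")
  }
  grad
}

#' Fit a mixture-of-Gaussians embedding prior by EM
#'
#' Fits a `C`-component diagonal-Gaussian mixture to a set of compressed
#' embedding vectors (in the full pipeline: embeddings of residues found
#' in densely populated alignment columns, see [densColumnEmbeddings()]).
#' Initialization is k-means++ seeding; EM runs until the relative
#' log-likelihood change falls below `tol` or `maxIter` is reached.
#' Component variances are clamped at the variance floor so degenerate
#' inputs cannot crash the fit.
#'
#' @param x `N x r` matrix (or list of length-`r` vectors) of embeddings.
#' @param C number of components.
#' @param seed RNG seed (the fit is deterministic given the seed).
#' @param maxIter,tol EM iteration cap and relative tolerance.
#' @return an [EmbeddingPrior-class]; the attribute `"logLikTrace"` holds
#'   the (non-decreasing) EM log-likelihood trace.
#' @export
fitEmbeddingPrior <- function(x, C, seed = 1L, maxIter = 200L, tol = 1e-6) {
  if (is.list(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (C < 1L) stop("C must be >= 1")
  N <- nrow(x); r <- ncol(x)
  if (N < C) stop("need at least C embedding vectors")
  centers <- withLocalSeed(childSeed(seed, "kmeanspp"), kmeansppSeed(x, C))
  weights <- rep(1 / C, C)
  vars <- matrix(pmax(rep(apply(x, 2L, function(col) mean((col - mean(col))^2)),
                          each = C), VAR_FLOOR), C, r)
  means <- centers
  prior <- new("EmbeddingPrior", weights = weights, mean = means, var = vars)
  ll <- -Inf; trace <- numeric(0L)
  for (iter in seq_len(maxIter)) {
    comp <- componentLogDensities(x, prior)
    rowLse <- rowLogSumExp(comp)
    newLL <- sum(rowLse)
    trace <- c(trace, newLL)
    resp <- exp(comp - rowLse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    weights <- nk / sum(nk)
    means <- sweep(t(resp) %*% x, 1L, nk, "/")
    vars <- matrix(0, C, r)
    for (c in seq_len(C)) {
      d2 <- sweep(x, 2L, means[c, ])^2
      vars[c, ] <- colSums(resp[, c] * d2) / nk[c]
    }
    vars <- pmax(vars, VAR_FLOOR)
    prior <- new("EmbeddingPrior", weights = weights, mean = means,
                 var = vars)
    if (is.finite(ll) && abs(newLL - ll) <= tol * (abs(ll) + 1e-12)) break
    ll <- newLL
  }
  attr(prior, "logLikTrace") <- trace
  prior
}

## k-means++ seeding followed by a few Lloyd iterations
kmeansppSeed <- function(x, C) {
  N <- nrow(x)
  centers <- matrix(0, C, ncol(x))
  idx <- sample.int(N, 1L)
  centers[1L, ] <- x[idx, ]
  if (C > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (c in 2:C) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / N, N)
      idx <- sample.int(N, 1L, prob = p)
      centers[c, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[c, ])^2))
    }
  }
  ## Lloyd refinement; degenerate seeds (duplicate centers) keep the seeding
  tryCatch(
    suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 10L)$centers),
    error = function(e) centers)
}

#' Embeddings of residues in densely populated alignment columns
#'
#' Selects, from a reference alignment, the residues that sit in columns
#' with at most 50% gaps and returns their compressed embeddings; the
#' training set for [fitEmbeddingPrior()].
#'
#' @param msa a [ProfileMSA-class].
#' @param compressed named list mapping row identifiers to `L x r`
#'   compressed embedding matrices (ungapped coordinates).
#' @param maxGapFrac gap-fraction threshold defining "densely populated".
#' @return matrix with one row per selected residue.
#' @export
densColumnEmbeddings <- function(msa, compressed, maxGapFrac = 0.5) {
  mat <- msaMatrix(msa)
  isGap <- mat == "-" | mat == "."
  dense <- colMeans(isGap) <= maxGapFrac
  resIdx <- t(apply(isGap, 1L, function(g) cumsum(!g)))
  rows <- list()
  for (a in seq_len(nrow(mat))) {
    id <- msa@ids[a]
    emb <- compressed[[id]]
    if (is.null(emb)) stop("no embeddings for row ", id)
    sel <- dense & !isGap[a, ]
    if (any(sel)) rows[[length(rows) + 1L]] <- emb[resIdx[a, sel], , drop = FALSE]
  }
  do.call(rbind, rows)
}

#' Initialize embedding emissions by sampling the prior
#'
#' Each match-state mean is drawn from the mixture; its variances start at
#' the sampled component's variances, so initial states resemble
#' embeddings the embedder actually produces. The insert/flank background
#' Gaussian is moment-matched to the prior and frozen.
#'
#' @param prior an [EmbeddingPrior-class].
#' @param nMatch number of match states.
#' @param seed RNG seed; sampling is deterministic given the seed.
#' @param tau temperature for the resulting emission model.
#' @return an [EmbeddingEmissions-class].
#' @export
initEmissionsFromPrior <- function(prior, nMatch, seed = 1L, tau = 1) {
  validObject(prior)
  r <- ncol(prior@mean)
  mm <- momentMatchPrior(prior)
  withLocalSeed(childSeed(seed, "emission-init"), {
    comp <- sample.int(length(prior@weights), nMatch, replace = TRUE,
                       prob = prior@weights)
    mean <- prior@mean[comp, , drop = FALSE] +
      matrix(rnorm(nMatch * r), nMatch, r) *
        sqrt(prior@var[comp, , drop = FALSE])
    var <- prior@var[comp, , drop = FALSE]
    makeEmbeddingEmissions(mean, var, tau = tau,
                           bgMean = mm$mean, bgVar = mm$var)
  })
}

#' Moment-matched background Gaussian of an embedding prior
#'
#' Mean = mixture mean; variance = total mixture variance (within- plus
#' between-component). Used as the frozen insert/flank embedding density.
#'
#' @param prior an [EmbeddingPrior-class].
#' @return list with `mean` and `var` (length-`r` vectors).
#' @export
momentMatchPrior <- function(prior) {
  w <- prior@weights
  mean <- as.vector(t(prior@mean) %*% w)
  second <- as.vector(t(prior@var + prior@mean^2) %*% w)
  list(mean = mean, var = pmax(second - mean^2, VAR_FLOOR))
}

#' Serialize an embedding prior to JSON
#' @param prior an [EmbeddingPrior-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEmbeddingPrior <- function(prior, path) {
  validObject(prior)
  jsonlite::write_json(list(
    schema = paste0("dphmm-embedding-prior-", SCHEMA_VERSION),
    weights = prior@weights, mean = prior@mean, var = prior@var
  ), path, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read an embedding prior from JSON
#' @param path file written by [writeEmbeddingPrior()].
#' @return an [EmbeddingPrior-class].
#' @export
readEmbeddingPrior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, paste0("dphmm-embedding-prior-", SCHEMA_VERSION)))
    stop("unsupported schema: ", obj$schema)
  C <- length(obj$weights)
  new("EmbeddingPrior", weights = as.numeric(obj$weights),
      mean = matrix(as.numeric(obj$mean), nrow = C),
      var = matrix(as.numeric(obj$var), nrow = C))
}
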