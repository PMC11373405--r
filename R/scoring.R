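## Low-rank bilinear scoring model: residue-pair alignment probabilities
## in training mode, embedding compression in inference mode. The factor R
## defines both: scores are sigmoid(embS R (embT R)^T) and the compressor
## is emb -> emb R, so W = R R^T never has to be materialized.

#' Construct a scoring model
#'
#' @param d embedding dimension.
#' @param r rank of the factor (must satisfy `r < d`).
#' @param seed seed for the Gaussian initialization of `R` (entries have
#'   standard deviation `1/sqrt(d)`).
#' @param R optional explicit `d x r` factor (overrides `d`, `r`, `seed`).
#' @return a [ScoringModel-class].
#' @export
makeScoringModel <- function(d, r, seed = 1L, R = NULL) {
  if (is.null(R)) {
    if (r >= d) stop("low-rank requirement: r must be < d")
    R <- withLocalSeed(childSeed(seed, "scoring-init"),
                       matrix(rnorm(d * r, sd = 1 / sqrt(d)), d, r))
  }
  new("ScoringModel", R = as.matrix(R), activation = "logistic-sigmoid")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Residue-pair alignment probability matrix
#'
#' `A = sigmoid(embS R (embT R)^T)`: entry `(i, j)` is the predicted
#' probability that residue `i` of the first sequence aligns with residue
#' `j` of the second.
#'
#' @param embS,embT `L1 x d` and `L2 x d` embedding matrices.
#' @param model a [ScoringModel-class].
#' @return `L1 x L2` matrix with entries in `(0, 1)`.
#' @export
scoreMatrix <- function(embS, embT, model) {
  embS <- as.matrix(embS); embT <- as.matrix(embT)
  d <- nrow(model@R)
  if (ncol(embS) != d || ncol(embT) != d)
    stop("embedding dimension does not match the scoring model")
  sigmoid(tcrossprod(embS %*% model@R, embT %*% model@R))
}

#' Compress embeddings to the low-rank space
#'
#' Inference mode of the scoring model: `emb %*% R`. By construction
#' `scoreMatrix(embS, embT)` equals the sigmoid of the inner products of
#' the compressed rows, so profile training never needs the raw
#' `d`-dimensional vectors.
#'
#' @param emb `L x d` embedding matrix.
#' @param model a [ScoringModel-class].
#' @return `L x r` compressed matrix.
#' @export
compressEmbeddings <- function(emb, model) {
  emb <- as.matrix(emb)
  if (ncol(emb) != nrow(model@R))
    stop("embedding dimension does not match the scoring model")
  emb %*% model@R
}

#' Number of trainable parameters of a scoring model
#'
#' The low-rank factor only (`d * r`); the full `d x d` bilinear form is
#' never materialized or trained.
#'
#' @param model a [ScoringModel-class].
#' @return integer count.
#' @export
parameterCount <- function(model) {
  as.integer(nrow(model@R) * ncol(model@R))
}

#' Binary target matrix of a pairwise alignment
#'
#' @param pairs `k x 2` matrix of aligned 0-based residue index pairs (or
#'   the list form produced by [inducePairwiseAlignments()]).
#' @param L1,L2 sequence lengths.
#' @return `L1 x L2` binary matrix with 1 at each aligned pair.
#' @export
pairTargetMatrix <- function(pairs, L1, L2) {
  if (is.list(pairs) && !is.null(pairs$pairs)) pairs <- pairs$pairs
  target <- matrix(0, L1, L2)
  if (NROW(pairs) == 0L) return(target)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1L] < 0L) || any(pairs[, 1L] >= L1) ||
      any(pairs[, 2L] < 0L) || any(pairs[, 2L] >= L2))
    stop("alignment pair index out of range")
  target[cbind(pairs[, 1L] + 1L, pairs[, 2L] + 1L)] <- 1
  target
}

#' Weighted binary cross-entropy between scores and targets
#'
#' Mean over entries of `-[w t log A + (1 - t) log(1 - A)]` with weight
#' `w = posWeight` on the positive entries; scores are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param A score matrix (entries in `(0, 1)`).
#' @param target binary matrix of the same shape.
#' @param posWeight weight applied to positive (aligned) entries;
#'   counteracts the `O(L)` positives vs `O(L^2)` negatives imbalance.
#' @return scalar loss.
#' @export
bceLoss <- function(A, target, posWeight = 1) {
  if (!all(dim(A) == dim(target))) stop("shape mismatch")
  A <- pmin(pmax(A, 1e-7), 1 - 1e-7)
  mean(-(posWeight * target * log(A) + (1 - target) * log1p(-A)))
}

## gradient of bceLoss w.r.t. R for one pair (embS, embT, target)
bceGradR <- function(embS, embT, target, R, posWeight) {
  cS <- embS %*% R; cT <- embT %*% R
  A <- sigmoid(tcrossprod(cS, cT))
  Ac <- pmin(pmax(A, 1e-7), 1 - 1e-7)
  ## dL/dZ with Z the logit matrix, including the clamp's dead zone
  G <- (-(posWeight * target * (1 - Ac) - (1 - target) * Ac) *
          (A > 1e-7 & A < 1 - 1e-7)) / length(A)
  list(grad = crossprod(embS, G %*% cT) + crossprod(embT, t(G) %*% cS),
       loss = mean(-(posWeight * target * log(Ac) + (1 - target) * log1p(-Ac))))
}

#' Pretrain a scoring model on induced pairwise alignments
#'
#' Casts scoring as independent binary classification of residue pairs:
#' each training item is a pair of embedded sequences plus the binary
#' target matrix of their induced alignment, and only the low-rank factor
#' `R` receives gradients (Adam, one sequence-pair matrix per step).
#' Positives are upweighted by the per-pair negative/positive ratio by
#' default, since a trivial all-negative predictor dominates otherwise.
#'
#' @param pairs list of training items, each a list with `embS`, `embT`
#'   (`L x d` embedding matrices) and `pairs` (aligned index pairs as in
#'   [pairTargetMatrix()]).
#' @param r rank of the factor.
#' @param epochs number of passes over the training pairs.
#' @param lr Adam learning rate.
#' @param seed seed for initialization and epoch shuffling.
#' @param posWeight positive-class weight, or `NULL` for the per-pair
#'   negative/positive ratio.
#' @return a [ScoringModel-class]; attribute `"lossTrace"` holds the mean
#'   per-epoch training loss.
#' @export
pretrainScoringModel <- function(pairs, r, epochs = 30L, lr = 1e-3,
                                 seed = 1L, posWeight = NULL) {
  if (length(pairs) < 1L) stop("at least one training pair required")
  d <- ncol(pairs[[1L]]$embS)
  if (r >= d) stop("low-rank requirement: r must be < d")
  model <- makeScoringModel(d, r, seed = seed)
  R <- model@R
  targets <- lapply(pairs, function(p)
    pairTargetMatrix(p$pairs, nrow(p$embS), nrow(p$embT)))
  weights <- vapply(seq_along(pairs), function(k) {
    if (!is.null(posWeight)) return(as.numeric(posWeight))
    np <- sum(targets[[k]])
    if (np == 0) 1 else (length(targets[[k]]) - np) / np
  }, numeric(1L))
  trace <- numeric(0L)
  opt <- adamInit(list(R = R))
  withLocalSeed(childSeed(seed, "scoring-shuffle"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(pairs))
      losses <- numeric(length(pairs))
      for (k in ord) {
        p <- pairs[[k]]
        g <- bceGradR(p$embS, p$embT, targets[[k]], R, weights[k])
        losses[k] <- g$loss
        step <- adamStep(opt, list(R = R), list(R = g$grad), lr)
        opt <- step$state
        R <- step$par$R
      }
      trace <- c(trace, mean(losses))
    }
  })
  out <- new("ScoringModel", R = R, activation = "logistic-sigmoid")
  attr(out, "lossTrace") <- trace
  out
}

#' Serialize a scoring model to JSON
#' @param model a [ScoringModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScoringModel <- function(model, path) {
  validObject(model)
  jsonlite::write_json(list(
    schema = paste0("dphmm-scoring-", SCHEMA_VERSION),
    d = nrow(model@R), r = ncol(model@R),
    activation = model@activation, R = model@R
  ), path, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a scoring model from JSON
#' @param path file written by [writeScoringModel()].
#' @return a [ScoringModel-class].
#' @export
readScoringModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, paste0("dphmm-scoring-", SCHEMA_VERSION)))
    stop("unsupported schema: ", obj$schema)
  new("ScoringModel",
      R = matrix(as.numeric(obj$R), nrow = as.integer(obj$d)),
      activation = obj$activation)
}
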