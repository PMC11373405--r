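# Numerical helpers shared across the package. All dynamic programming is
# done in log space; these primitives must be stable for arguments near -Inf.

#' @importFrom stats rnorm runif setNames kmeans median sd dnorm
#' @importFrom utils head tail modifyList
NULL

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
UNKNOWN_CODE_OFFSET <- 1L  # 'X' is encoded as length(alphabet) + 1
PROB_FLOOR <- 1e-16
VAR_FLOOR <- 1e-6
SCHEMA_VERSION <- "1.0"

## elementwise log(exp(a) + exp(b)) for vectors/matrices, -Inf safe
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  d <- pmin(a, b) - m
  out <- m + log1p(exp(d))
  # both -Inf -> NaN from (-Inf) - (-Inf); the sum is then -Inf
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

## row-wise logsumexp of a matrix
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  finite <- is.finite(m)
  out <- rep(-Inf, nrow(x))
  if (any(finite)) {
    xs <- x[finite, , drop = FALSE] - m[finite]
    out[finite] <- m[finite] + log(rowSums(exp(xs)))
  }
  out
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## row-wise softmax
rowSoftmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(x)))
}

## inverse of softplus, for initializing unconstrained scale parameters
softplusInv <- function(y) {
  ifelse(y > 30, y, log(expm1(y)))
}

floorLog <- function(p) log(pmax(p, PROB_FLOOR))

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

## Run an expression with a locally seeded RNG, restoring global state.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Derive a child seed from a base seed and a stream label (stays < 2^31).
childSeed <- function(seed, stream) {
  h <- stringHash31(paste0("seed:", seed, ":", stream))
  (h %% 2147483562L) + 1L
}

## Deterministic 31-bit string hash (polynomial rolling hash mod a prime).
stringHash31 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

## Content hash of a numeric object, used for cache provenance tags.
numericHash <- function(x) {
  stringHash31(paste(sprintf("%.10e", as.numeric(x)), collapse = ","))
}

adamInit <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

## One Adam step; `par` and `grad` are conformable lists of numerics.
## Maximizes when `maximize` is TRUE (ascent on the objective).
adamStep <- function(state, par, grad, lr, maximize = FALSE,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  sgn <- if (maximize) 1 else -1
  for (k in names(par)) {
    g <- grad[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    lrk <- if (is.list(lr)) {
      if (!is.null(lr[[k]])) lr[[k]] else lr[["default"]]
    } else lr
    par[[k]] <- par[[k]] + sgn * lrk * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, par = par)
}
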