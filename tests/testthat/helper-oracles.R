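# Independent oracles used across the suite. These deliberately avoid the
# package's dynamic programs and vectorized kernels: the path oracle walks
# the explicit state graph recursively, and the score oracles enumerate
# residue pairs and columns with plain loops.

## All complete-path probabilities of a sequence under a profile HMM,
## by explicit recursive enumeration of the state graph.
oraclePathProbs <- function(hmm, seq, extra = NULL) {
  batch <- encodeSequences(setNames(seq, "s"), hmm@alphabet)
  codes <- batch@codes[1, ]
  L <- length(codes); LM <- nMatch(hmm); A <- length(hmm@alphabet)
  tp <- transitionProbs(hmm)
  eMat <- cbind(matchEmissions(hmm), 1 / A)
  eBg <- c(insertEmissions(hmm), 1 / A)
  exM <- if (!is.null(extra)) exp(extra$match[[1]]) else matrix(1, LM, L)
  exI <- if (!is.null(extra) && !is.null(extra$insert))
    exp(extra$insert[[1]]) else rep(1, L)
  probs <- c()
  rec <- function(state, i, pos, p) {
    if (p == 0) return()
    if (state == "B") {
      if (pos < L) rec("N", 0, pos + 1,
                       p * tp$begin[["flankL"]] * eBg[codes[pos + 1]] * exI[pos + 1])
      rec("BB", 0, pos, p * tp$begin[["body"]])
    } else if (state == "N") {
      if (pos < L) rec("N", 0, pos + 1,
                       p * tp$flankL[["loop"]] * eBg[codes[pos + 1]] * exI[pos + 1])
      rec("BB", 0, pos, p * tp$flankL[["body"]])
    } else if (state == "BB") {
      if (pos < L) rec("M", 1, pos + 1,
                       p * tp$entry[["M1"]] * eMat[1, codes[pos + 1]] * exM[1, pos + 1])
      rec("D", 1, pos, p * tp$entry[["D1"]])
    } else if (state == "M") {
      if (i == LM) rec("BE", 0, pos, p)
      else {
        if (pos < L) {
          rec("M", i + 1, pos + 1,
              p * tp$match[i, "toM"] * eMat[i + 1, codes[pos + 1]] * exM[i + 1, pos + 1])
          rec("I", i, pos + 1,
              p * tp$match[i, "toI"] * eBg[codes[pos + 1]] * exI[pos + 1])
        }
        rec("D", i + 1, pos, p * tp$match[i, "toD"])
      }
    } else if (state == "I") {
      if (pos < L) {
        rec("M", i + 1, pos + 1,
            p * tp$insert[i, "toM"] * eMat[i + 1, codes[pos + 1]] * exM[i + 1, pos + 1])
        rec("I", i, pos + 1,
            p * tp$insert[i, "loop"] * eBg[codes[pos + 1]] * exI[pos + 1])
      }
    } else if (state == "D") {
      if (i == LM) rec("BE", 0, pos, p)
      else {
        if (pos < L) rec("M", i + 1, pos + 1,
                         p * tp$delete[i, "toM"] * eMat[i + 1, codes[pos + 1]] * exM[i + 1, pos + 1])
        rec("D", i + 1, pos, p * tp$delete[i, "toD"])
      }
    } else if (state == "BE") {
      if (pos < L) rec("Cst", 0, pos + 1,
                       p * tp$exit[["flankR"]] * eBg[codes[pos + 1]] * exI[pos + 1])
      if (pos == L) probs <<- c(probs, p * tp$exit[["end"]])
    } else if (state == "Cst") {
      if (pos < L) rec("Cst", 0, pos + 1,
                       p * tp$flankR[["loop"]] * eBg[codes[pos + 1]] * exI[pos + 1])
      if (pos == L) probs <<- c(probs, p * tp$flankR[["end"]])
    }
  }
  rec("B", 0, 0, 1)
  probs
}

## random small profile HMM over a 3-letter toy alphabet
randomToyHMM <- function(LM, seed, alphabet = c("A", "C", "D")) {
  A <- length(alphabet)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    k <- max(LM - 1, 0)
    tl <- list(
      begin = rnorm(2), flankL = rnorm(2), entry = rnorm(2),
      match = matrix(rnorm(k * 3), k, 3),
      insert = matrix(rnorm(k * 2), k, 2),
      delete = matrix(rnorm(k * 2), k, 2),
      exit = rnorm(2), flankR = rnorm(2))
    makeProfileHMM(LM, alphabet = alphabet,
                   matchLogits = matrix(rnorm(LM * A), LM, A),
                   insertLogits = rnorm(A), transLogits = tl)
  })
}

## random toy alignment over up to maxRows rows; returns a ProfileMSA
randomToyMSA <- function(nrows, ncols, seed) {
  set.seed(seed)
  repeat {
    mat <- matrix(sample(c("A", "C", "D", "E", "-"), nrows * ncols,
                         replace = TRUE, prob = c(rep(0.2, 4), 0.2)),
                  nrows, ncols)
    ## every row needs at least one residue; drop all-gap columns
    if (any(apply(mat, 1, function(r) all(r == "-")))) next
    keep <- apply(mat, 2, function(col) any(col != "-"))
    mat <- mat[, keep, drop = FALSE]
    if (ncol(mat) >= 1) break
  }
  new("ProfileMSA", ids = paste0("r", seq_len(nrows)),
      rows = apply(mat, 1, paste, collapse = ""),
      isMatch = rep(TRUE, ncol(mat)))
}

## same ungapped content, re-gapped at random (valid comparable prediction)
shuffleAlignment <- function(ref, seed) {
  set.seed(seed)
  seqs <- ungappedSequences(ref)
  w <- max(nchar(seqs)) + sample(0:3, 1)
  rows <- vapply(seqs, function(s) {
    L <- nchar(s)
    slots <- sort(sample(w, L))
    out <- rep("-", w)
    out[slots] <- strsplit(s, "")[[1]]
    paste(out, collapse = "")
  }, character(1))
  keep <- which(colSums(do.call(rbind, strsplit(rows, "")) != "-") > 0)
  mat <- do.call(rbind, strsplit(rows, ""))[, keep, drop = FALSE]
  new("ProfileMSA", ids = ref@ids,
      rows = apply(mat, 1, paste, collapse = ""),
      isMatch = rep(TRUE, length(keep)))
}

## brute-force SP: loop over all residue pairs of the reference
oracleSP <- function(pred, ref) {
  colOf <- function(msa) {
    mat <- do.call(rbind, strsplit(msaRows(msa), ""))
    lapply(seq_len(nrow(mat)), function(a) which(!(mat[a, ] %in% c("-", "."))))
  }
  cp <- colOf(pred); cr <- colOf(ref)
  predIdx <- match(ref@ids, pred@ids)
  n <- length(ref@ids)
  total <- 0; hit <- 0
  for (a in seq_len(n - 1)) for (b in seq.int(a + 1, n)) {
    for (i in seq_along(cr[[a]])) for (j in seq_along(cr[[b]])) {
      if (cr[[a]][i] == cr[[b]][j]) {
        total <- total + 1
        pa <- predIdx[a]; pb <- predIdx[b]
        if (cp[[pa]][i] == cp[[pb]][j]) hit <- hit + 1
      }
    }
  }
  if (total == 0) return(0)
  100 * hit / total
}

## brute-force TC and weighted column score via explicit column sets
oracleColumns <- function(pred, ref) {
  colSets <- function(msa) {
    mat <- do.call(rbind, strsplit(msaRows(msa), ""))
    idx <- matrix(NA_integer_, nrow(mat), ncol(mat))
    for (a in seq_len(nrow(mat))) {
      res <- which(!(mat[a, ] %in% c("-", ".")))
      idx[a, res] <- seq_along(res)
    }
    lapply(seq_len(ncol(mat)), function(cc) {
      filled <- which(!is.na(idx[, cc]))
      if (!length(filled)) return(NULL)
      s <- paste(sort(paste0(msa@ids[filled], "=", idx[filled, cc])),
                 collapse = ";")
      list(key = s, m = length(filled))
    })
  }
  rc <- Filter(Negate(is.null), colSets(ref))
  pc <- Filter(Negate(is.null), colSets(pred))
  predKeys <- vapply(pc, `[[`, character(1), "key")
  matched <- vapply(rc, function(x) x$key %in% predKeys, logical(1))
  m <- vapply(rc, `[[`, numeric(1), "m")
  pairs <- m * (m - 1) / 2
  list(tc = 100 * mean(matched),
       column = if (sum(pairs) > 0) 100 * sum(pairs[matched]) / sum(pairs)
                else NA_real_)
}

## rank-based AUROC (Mann-Whitney)
aurocOf <- function(scores, labels) {
  r <- rank(scores)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

## optimal one-to-one matching of emission rows by mean total variation
## (exhaustive over permutations; fine for <= 8 states)
meanTVAfterMatching <- function(trueE, estE) {
  n <- nrow(trueE)
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  cost <- outer(seq_len(n), seq_len(n),
                Vectorize(function(i, j) tv(trueE[i, ], estE[j, ])))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) mean(cost[cbind(seq_len(n), p)]), numeric(1)))
}
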