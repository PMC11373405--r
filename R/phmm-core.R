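## Profile HMM core: construction, encoding, the batched log-space forward
## algorithm (the differentiable likelihood), the backward pass with
## posterior expected counts (which yield exact gradients of the forward
## log-likelihood with respect to all unconstrained parameters), and
## Viterbi decoding.
##
## State layout. Emitting states: left flank N, matches M_1..M_L, inserts
## I_1..I_{L-1}, right flank C. Silent states: begin B, body-begin BB,
## deletes D_1..D_L, body-end BE, end E. Delete chains are resolved within
## each sequence position by iterating the match index in order, which is
## the classic 2D profile recursion.

#' Batch of integer-encoded sequences
#'
#' @slot codes `n x Lmax` integer matrix, `NA`-padded; residues are coded
#'   `1..A` in alphabet order and `A+1` for the unknown residue `X`.
#' @slot lengths per-sequence lengths.
#' @slot ids sequence identifiers.
#' @export
setClass("EncodedBatch",
  representation(codes = "matrix", lengths = "integer", ids = "character")
)

setValidity("EncodedBatch", function(object) {
  msg <- character()
  n <- nrow(object@codes)
  if (length(object@lengths) != n || length(object@ids) != n)
    msg <- c(msg, "lengths and ids must have one entry per row")
  if (any(object@lengths < 1L)) msg <- c(msg, "empty sequence in batch")
  for (s in seq_len(n)) {
    L <- object@lengths[s]
    row <- object@codes[s, ]
    if (any(is.na(row[seq_len(L)])) ||
        (L < ncol(object@codes) && any(!is.na(row[-seq_len(L)])))) {
      msg <- c(msg, "padding mask inconsistent with lengths")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Encode sequences for the profile HMM dynamic programs
#'
#' @param seqs named character vector of residue strings (as returned by
#'   [readProteinFasta()]).
#' @param alphabet residue alphabet; defaults to the 20 amino acids.
#' @return an [EncodedBatch-class].
#' @export
encodeSequences <- function(seqs, alphabet = AA_LETTERS) {
  if (length(seqs) == 0L) stop("no sequences to encode")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence: ",
                            paste(names(seqs)[lens == 0L], collapse = ", "))
  codes <- matrix(NA_integer_, length(seqs), max(lens))
  lookup <- setNames(seq_along(alphabet), alphabet)
  unknown <- length(alphabet) + UNKNOWN_CODE_OFFSET
  for (s in seq_along(seqs)) {
    ch <- strsplit(seqs[[s]], "", fixed = TRUE)[[1L]]
    v <- unname(lookup[ch])
    v[is.na(v)] <- unknown
    codes[s, seq_len(lens[s])] <- v
  }
  new("EncodedBatch", codes = codes, lengths = as.integer(lens),
      ids = names(seqs))
}

#' Construct a profile HMM
#'
#' Builds a [ProfileHMM-class] with the given unconstrained parameters, or
#' with near-neutral defaults: match emission logits are small seeded
#' Gaussian perturbations around the uniform distribution, the insert
#' distribution is the uniform background, and transitions favour the
#' match chain (match-to-match probability about 0.9, small indel rates).
#'
#' @param nMatch number of match states.
#' @param alphabet residue alphabet.
#' @param seed seed for the emission perturbations.
#' @param matchLogits,insertLogits,transLogits optional explicit
#'   unconstrained parameters (see [ProfileHMM-class]).
#' @return a [ProfileHMM-class].
#' @export
makeProfileHMM <- function(nMatch, alphabet = AA_LETTERS, seed = 1L,
                           matchLogits = NULL, insertLogits = NULL,
                           transLogits = NULL) {
  nMatch <- as.integer(nMatch)
  A <- length(alphabet)
  if (is.null(matchLogits)) {
    matchLogits <- withLocalSeed(childSeed(seed, "match-init"),
      matrix(rnorm(nMatch * A, sd = 0.1), nMatch, A))
  }
  if (is.null(insertLogits)) insertLogits <- rep(0, A)
  if (is.null(transLogits)) transLogits <- defaultTransLogits(nMatch)
  new("ProfileHMM", nMatch = nMatch, alphabet = alphabet,
      matchLogits = matchLogits, insertLogits = insertLogits,
      transLogits = transLogits)
}

defaultTransLogits <- function(nMatch) {
  lg <- function(p) log(p)  # logits as log-probabilities (softmax-invariant)
  k <- max(nMatch - 1L, 0L)
  list(
    begin  = lg(c(0.2, 0.8)),
    flankL = lg(c(0.6, 0.4)),
    entry  = lg(c(0.95, 0.05)),
    match  = matrix(rep(lg(c(0.9, 0.05, 0.05)), each = k), k, 3L),
    insert = matrix(rep(lg(c(0.5, 0.5)), each = k), k, 2L),
    delete = matrix(rep(lg(c(0.7, 0.3)), each = k), k, 2L),
    exit   = lg(c(0.2, 0.8)),
    flankR = lg(c(0.6, 0.4))
  )
}

## Log emission tables. Match: nMatch x (A+1); insert: length A+1. The
## unknown residue X (code A+1) is emitted with probability 1/A at every
## emitting state (uniform background), carrying no gradient.
matchLogProbs <- function(hmm) {
  p <- rowSoftmax(hmm@matchLogits)
  cbind(floorLog(p), log(1 / length(hmm@alphabet)))
}

insertLogProbs <- function(hmm) {
  p <- softmax(hmm@insertLogits)
  c(floorLog(p), log(1 / length(hmm@alphabet)))
}

## Flat list of transition log-probabilities used by the dynamic programs.
transLogTable <- function(hmm) {
  tp <- transitionProbs(hmm)
  f <- floorLog
  list(
    bN = f(tp$begin[["flankL"]]), bB = f(tp$begin[["body"]]),
    nn = f(tp$flankL[["loop"]]), nb = f(tp$flankL[["body"]]),
    eM = f(tp$entry[["M1"]]), eD = f(tp$entry[["D1"]]),
    mm = f(tp$match[, "toM"]), mi = f(tp$match[, "toI"]),
    md = f(tp$match[, "toD"]),
    im = f(tp$insert[, "toM"]), ii = f(tp$insert[, "loop"]),
    dm = f(tp$delete[, "toM"]), dd = f(tp$delete[, "toD"]),
    xc = f(tp$exit[["flankR"]]), xe = f(tp$exit[["end"]]),
    cc = f(tp$flankR[["loop"]]), ce = f(tp$flankR[["end"]])
  )
}

## add a length-k vector across the k columns of an n x k matrix
addCol <- function(x, v) x + rep(v, each = nrow(x))

logaddexp3 <- function(a, b, c) logaddexp(logaddexp(a, b), c)

## ---------------------------------------------------------------------------
## Batched forward (and optionally backward) over same-length sequences
## ---------------------------------------------------------------------------

## emM: n x LM x L match emission log-probs (extra term already added);
## emBg: n x L insert/flank emission log-probs. Returns log-likelihoods,
## and the full forward/backward tables when `keep = TRUE`.
batchForwardCore <- function(tl, emM, emBg, keep = FALSE) {
  n <- dim(emM)[1L]; LM <- dim(emM)[2L]; L <- dim(emM)[3L]
  NEG <- -Inf
  fN <- matrix(NEG, n, L + 1L); fBB <- matrix(NEG, n, L + 1L)
  fC <- matrix(NEG, n, L + 1L); fBE <- matrix(NEG, n, L + 1L)
  fM <- array(NEG, c(n, LM, L + 1L)); fD <- array(NEG, c(n, LM, L + 1L))
  fI <- array(NEG, c(n, max(LM - 1L, 1L), L + 1L))
  ## j = 0: nothing emitted; B has probability 1
  fBB[, 1L] <- tl$bB
  fD[, 1L, 1L] <- fBB[, 1L] + tl$eD
  if (LM > 1L) for (i in 2:LM)
    fD[, i, 1L] <- fD[, i - 1L, 1L] + tl$dd[i - 1L]
  fBE[, 1L] <- fD[, LM, 1L]
  for (j in seq_len(L)) {
    jj <- j + 1L
    eM <- emM[, , j]; dim(eM) <- c(n, LM)
    eB <- emBg[, j]
    Bprev <- if (j == 1L) 0 else NEG
    fN[, jj] <- eB + logaddexp(Bprev + tl$bN, fN[, jj - 1L] + tl$nn)
    fBB[, jj] <- fN[, jj] + tl$nb
    newM <- matrix(NEG, n, LM)
    newM[, 1L] <- eM[, 1L] + fBB[, jj - 1L] + tl$eM
    if (LM > 1L) {
      pre <- seq_len(LM - 1L)
      mPrev <- fM[, pre, jj - 1L]; dim(mPrev) <- c(n, LM - 1L)
      iPrev <- fI[, pre, jj - 1L]; dim(iPrev) <- c(n, LM - 1L)
      dPrev <- fD[, pre, jj - 1L]; dim(dPrev) <- c(n, LM - 1L)
      newM[, -1L] <- eM[, -1L, drop = FALSE] +
        logaddexp3(addCol(mPrev, tl$mm), addCol(iPrev, tl$im),
                   addCol(dPrev, tl$dm))
      fI[, pre, jj] <- eB +
        logaddexp(addCol(mPrev, tl$mi), addCol(iPrev, tl$ii))
    }
    fM[, , jj] <- newM
    newD <- matrix(NEG, n, LM)
    newD[, 1L] <- fBB[, jj] + tl$eD
    if (LM > 1L) for (i in 2:LM)
      newD[, i] <- logaddexp(newM[, i - 1L] + tl$md[i - 1L],
                             newD[, i - 1L] + tl$dd[i - 1L])
    fD[, , jj] <- newD
    fBE[, jj] <- logaddexp(newM[, LM], newD[, LM])
    fC[, jj] <- eB + logaddexp(fBE[, jj - 1L] + tl$xc, fC[, jj - 1L] + tl$cc)
  }
  logLik <- logaddexp(fBE[, L + 1L] + tl$xe, fC[, L + 1L] + tl$ce)
  if (!keep) return(list(logLik = logLik))
  list(logLik = logLik, fN = fN, fBB = fBB, fC = fC, fBE = fBE,
       fM = fM, fI = fI, fD = fD)
}

batchBackwardCore <- function(tl, emM, emBg) {
  n <- dim(emM)[1L]; LM <- dim(emM)[2L]; L <- dim(emM)[3L]
  NEG <- -Inf
  bN <- matrix(NEG, n, L + 1L); bBB <- matrix(NEG, n, L + 1L)
  bC <- matrix(NEG, n, L + 1L); bBE <- matrix(NEG, n, L + 1L)
  bM <- array(NEG, c(n, LM, L + 1L)); bD <- array(NEG, c(n, LM, L + 1L))
  bI <- array(NEG, c(n, max(LM - 1L, 1L), L + 1L))
  ## j = L: only silent continuations to the end state remain
  bC[, L + 1L] <- tl$ce
  bBE[, L + 1L] <- tl$xe
  bM[, LM, L + 1L] <- bBE[, L + 1L]
  bD[, LM, L + 1L] <- bBE[, L + 1L]
  if (LM > 1L) for (i in (LM - 1L):1L) {
    bD[, i, L + 1L] <- tl$dd[i] + bD[, i + 1L, L + 1L]
    bM[, i, L + 1L] <- tl$md[i] + bD[, i + 1L, L + 1L]
  }
  bBB[, L + 1L] <- tl$eD + bD[, 1L, L + 1L]
  bN[, L + 1L] <- tl$nb + bBB[, L + 1L]
  for (j in (L - 1L):0L) {
    jj <- j + 1L
    eM1 <- emM[, , j + 1L]; dim(eM1) <- c(n, LM)
    eB1 <- emBg[, j + 1L]
    bC[, jj] <- tl$cc + eB1 + bC[, jj + 1L]
    bBE[, jj] <- tl$xc + eB1 + bC[, jj + 1L]
    bM[, LM, jj] <- bBE[, jj]
    bD[, LM, jj] <- bBE[, jj]
    if (LM > 1L) for (i in (LM - 1L):1L) {
      toM <- eM1[, i + 1L] + bM[, i + 1L, jj + 1L]
      bD[, i, jj] <- logaddexp(tl$dm[i] + toM, tl$dd[i] + bD[, i + 1L, jj])
      bI[, i, jj] <- logaddexp(tl$im[i] + toM,
                               tl$ii[i] + eB1 + bI[, i, jj + 1L])
      bM[, i, jj] <- logaddexp3(tl$mm[i] + toM,
                                tl$mi[i] + eB1 + bI[, i, jj + 1L],
                                tl$md[i] + bD[, i + 1L, jj])
    }
    bBB[, jj] <- logaddexp(tl$eM + eM1[, 1L] + bM[, 1L, jj + 1L],
                           tl$eD + bD[, 1L, jj])
    bN[, jj] <- logaddexp(tl$nn + eB1 + bN[, jj + 1L], tl$nb + bBB[, jj])
  }
  list(bN = bN, bBB = bBB, bC = bC, bBE = bBE, bM = bM, bI = bI, bD = bD)
}

## Assemble emission log-prob tensors for one same-length group.
## extraM: n x LM x L array or NULL; extraI: n x L matrix or NULL.
groupEmissionTensors <- function(hmm, codes, extraM = NULL, extraI = NULL) {
  n <- nrow(codes); L <- ncol(codes); LM <- hmm@nMatch
  emTab <- matchLogProbs(hmm)          # LM x (A+1)
  bgTab <- insertLogProbs(hmm)         # A+1
  emM <- array(0, c(n, LM, L))
  for (j in seq_len(L)) emM[, , j] <- t(emTab)[codes[, j], , drop = FALSE]
  emBg <- matrix(bgTab[codes], n, L)
  if (!is.null(extraM)) emM <- emM + extraM
  if (!is.null(extraI)) emBg <- emBg + extraI
  list(emM = emM, emBg = emBg)
}

## Split an EncodedBatch (plus aligned extra terms) into same-length groups.
splitByLength <- function(batch, extra = NULL) {
  lens <- batch@lengths
  groups <- split(seq_along(lens), lens)
  lapply(groups, function(idx) {
    L <- lens[idx[1L]]
    codes <- batch@codes[idx, seq_len(L), drop = FALSE]
    g <- list(idx = idx, codes = codes, L = L)
    if (!is.null(extra)) {
      LM <- dim(extra$match[[idx[1L]]])[1L]
      exM <- array(0, c(length(idx), LM, L))
      exI <- matrix(0, length(idx), L)
      for (k in seq_along(idx)) {
        exM[k, , ] <- extra$match[[idx[k]]]
        if (!is.null(extra$insert)) exI[k, ] <- extra$insert[[idx[k]]]
      }
      g$extraM <- exM
      g$extraI <- exI
    }
    g
  })
}

#' Forward log-likelihood of sequences under a profile HMM
#'
#' Computes `log P(S) = log sum over state paths of P(path, S)` with the
#' log-space forward algorithm, batched over sequences. An optional extra
#' per-state, per-position emission term is added to the emission
#' log-probabilities before summation; this is the hook through which the
#' tempered embedding log-densities enter the joint emission model.
#'
#' @param hmm a [ProfileHMM-class].
#' @param batch an [EncodedBatch-class] or a (named) character vector of
#'   residue strings.
#' @param extraEmission optional list with elements `match` (per sequence,
#'   an `nMatch x L` matrix of extra match-state log-density terms) and
#'   optionally `insert` (per sequence, a length-`L` vector added to all
#'   insert/flank emissions); see [embeddingEmissionGrid()].
#' @return numeric vector of per-sequence log-likelihoods, in input order.
#' @export
forwardLogLik <- function(hmm, batch, extraEmission = NULL) {
  validObject(hmm)
  if (is.character(batch)) batch <- encodeSequences(batch, hmm@alphabet)
  checkExtra(hmm, batch, extraEmission)
  tl <- transLogTable(hmm)
  out <- numeric(nrow(batch@codes))
  for (g in splitByLength(batch, extraEmission)) {
    em <- groupEmissionTensors(hmm, g$codes, g$extraM, g$extraI)
    out[g$idx] <- batchForwardCore(tl, em$emM, em$emBg)$logLik
  }
  names(out) <- batch@ids
  out
}

checkExtra <- function(hmm, batch, extra) {
  if (is.null(extra)) return(invisible(NULL))
  if (is.null(extra$match) || length(extra$match) != nrow(batch@codes))
    stop("extraEmission$match must have one matrix per sequence")
  for (s in seq_along(extra$match)) {
    m <- extra$match[[s]]
    if (!identical(dim(m), c(hmm@nMatch, as.integer(batch@lengths[s]))))
      stop("extraEmission$match[[", s, "]] must be nMatch x L")
    if (!all(is.finite(m)))
      stop("extraEmission contains non-finite values")
  }
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## Forward-backward: posterior expected counts and parameter gradients
## ---------------------------------------------------------------------------

## Returns the gradient of sum(logLik) over the batch with respect to all
## unconstrained HMM parameters, plus the match-state emission posteriors
## gamma (the gradient of sum(logLik) w.r.t. the extra match term), which
## drive the Gaussian embedding-parameter gradients.
forwardBackwardGrad <- function(hmm, batch, extraEmission = NULL) {
  tl <- transLogTable(hmm)
  LM <- hmm@nMatch
  A <- length(hmm@alphabet)
  gMatchCount <- matrix(0, LM, A); gMatchTot <- numeric(LM)
  gInsCount <- numeric(A); gInsTot <- 0
  cnt <- list(bn = 0, bb = 0, nn = 0, nb = 0, em = 0, ed = 0,
              mm = numeric(max(LM - 1L, 1L)), mi = numeric(max(LM - 1L, 1L)),
              md = numeric(max(LM - 1L, 1L)), im = numeric(max(LM - 1L, 1L)),
              ii = numeric(max(LM - 1L, 1L)), dm = numeric(max(LM - 1L, 1L)),
              dd = numeric(max(LM - 1L, 1L)), xc = 0, xe = 0, cc = 0, ce = 0)
  logLik <- numeric(nrow(batch@codes))
  gammaMatch <- vector("list", nrow(batch@codes))
  for (g in splitByLength(batch, extraEmission)) {
    em <- groupEmissionTensors(hmm, g$codes, g$extraM, g$extraI)
    emM <- em$emM; emBg <- em$emBg
    fw <- batchForwardCore(tl, emM, emBg, keep = TRUE)
    bw <- batchBackwardCore(tl, emM, emBg)
    lp <- fw$logLik
    logLik[g$idx] <- lp
    n <- length(g$idx); L <- g$L
    jsE <- seq_len(L)          # emitting-step columns (j = 1..L)
    ## --- emission posteriors -------------------------------------------
    gamM <- exp(fw$fM[, , jsE + 1L, drop = FALSE] +
                bw$bM[, , jsE + 1L, drop = FALSE] - c(lp))
    for (k in seq_len(n)) {
      gm <- gamM[k, , , drop = FALSE]; dim(gm) <- c(LM, L)
      gammaMatch[[g$idx[k]]] <- gm
    }
    codes <- g$codes
    known <- codes <= A
    ## match emission gradients: counts per symbol and totals
    flatG <- matrix(aperm(gamM, c(1L, 3L, 2L)), ncol = LM)  # (n*L) x LM
    cvec <- as.vector(codes)
    keep <- cvec <= A
    agg <- rowsum(flatG[keep, , drop = FALSE], group = cvec[keep])
    gMatchCount[, as.integer(rownames(agg))] <-
      gMatchCount[, as.integer(rownames(agg))] + t(agg)
    gMatchTot <- gMatchTot + colSums(flatG[keep, , drop = FALSE])
    ## insert/flank emission posteriors: N, I_i, C
    gamIns <- exp(fw$fN[, jsE + 1L] + bw$bN[, jsE + 1L] - lp) +
              exp(fw$fC[, jsE + 1L] + bw$bC[, jsE + 1L] - lp)
    if (LM > 1L) {
      gi <- exp(fw$fI[, , jsE + 1L, drop = FALSE] +
                bw$bI[, , jsE + 1L, drop = FALSE] - c(lp))
      gamIns <- gamIns + apply(gi, c(1L, 3L), sum)
    }
    aggI <- rowsum(as.vector(gamIns)[keep], group = cvec[keep])
    gInsCount[as.integer(rownames(aggI))] <-
      gInsCount[as.integer(rownames(aggI))] + aggI[, 1L]
    gInsTot <- gInsTot + sum(gamIns[known[, seq_len(L), drop = FALSE]])
    ## --- transition expected counts ------------------------------------
    jsAll <- seq_len(L + 1L)   # time indices jj = j+1 for j = 0..L
    jsPre <- seq_len(L)        # j = 0..L-1 (an emission follows)
    eB1 <- emBg                # emission of symbol j+1 for j = 0..L-1
    cnt$bn <- cnt$bn + sum(exp(tl$bN + emBg[, 1L] + bw$bN[, 2L] - lp))
    cnt$bb <- cnt$bb + sum(exp(tl$bB + bw$bBB[, 1L] - lp))
    cnt$nn <- cnt$nn +
      sum(exp(fw$fN[, jsPre] + tl$nn + eB1 + bw$bN[, jsPre + 1L] - lp))
    cnt$nb <- cnt$nb +
      sum(exp(fw$fN[, jsAll] + tl$nb + bw$bBB[, jsAll] - lp))
    eM1first <- matrix(emM[, 1L, ], n, L)
    cnt$em <- cnt$em + sum(exp(fw$fBB[, jsPre] + tl$eM + eM1first +
                               matrix(bw$bM[, 1L, jsPre + 1L], n, L) - lp))
    cnt$ed <- cnt$ed + sum(exp(fw$fBB[, jsAll] + tl$eD +
                               matrix(bw$bD[, 1L, jsAll], n, L + 1L) - lp))
    if (LM > 1L) for (i in seq_len(LM - 1L)) {
      fMi <- matrix(fw$fM[, i, jsPre], n, L)
      fIi <- matrix(fw$fI[, i, jsPre], n, L)
      fDiP <- matrix(fw$fD[, i, jsPre], n, L)
      eMn <- matrix(emM[, i + 1L, ], n, L)
      bMn <- matrix(bw$bM[, i + 1L, jsPre + 1L], n, L)
      bIi <- matrix(bw$bI[, i, jsPre + 1L], n, L)
      toM <- eMn + bMn
      cnt$mm[i] <- cnt$mm[i] + sum(exp(fMi + tl$mm[i] + toM - lp))
      cnt$mi[i] <- cnt$mi[i] + sum(exp(fMi + tl$mi[i] + eB1 + bIi - lp))
      cnt$im[i] <- cnt$im[i] + sum(exp(fIi + tl$im[i] + toM - lp))
      cnt$ii[i] <- cnt$ii[i] + sum(exp(fIi + tl$ii[i] + eB1 + bIi - lp))
      cnt$dm[i] <- cnt$dm[i] + sum(exp(fDiP + tl$dm[i] + toM - lp))
      ## silent targets: same time index, j = 0..L
      fMiA <- matrix(fw$fM[, i, jsAll], n, L + 1L)
      fDiA <- matrix(fw$fD[, i, jsAll], n, L + 1L)
      bDn <- matrix(bw$bD[, i + 1L, jsAll], n, L + 1L)
      cnt$md[i] <- cnt$md[i] + sum(exp(fMiA + tl$md[i] + bDn - lp))
      cnt$dd[i] <- cnt$dd[i] + sum(exp(fDiA + tl$dd[i] + bDn - lp))
    }
    cnt$xc <- cnt$xc +
      sum(exp(fw$fBE[, jsPre] + tl$xc + eB1 + bw$bC[, jsPre + 1L] - lp))
    cnt$xe <- cnt$xe + sum(exp(fw$fBE[, L + 1L] + tl$xe - lp))
    cnt$cc <- cnt$cc +
      sum(exp(fw$fC[, jsPre] + tl$cc + eB1 + bw$bC[, jsPre + 1L] - lp))
    cnt$ce <- cnt$ce + sum(exp(fw$fC[, L + 1L] + tl$ce - lp))
  }
  ## --- convert expected counts to gradients on the unconstrained logits --
  pMatch <- rowSoftmax(hmm@matchLogits)
  gMatch <- gMatchCount - pMatch * gMatchTot
  pIns <- softmax(hmm@insertLogits)
  gIns <- gInsCount - pIns * gInsTot
  tp <- transitionProbs(hmm)
  softmaxGroupGrad <- function(counts, probs) counts - probs * sum(counts)
  k <- max(LM - 1L, 0L)
  gTrans <- list(
    begin  = softmaxGroupGrad(c(cnt$bn, cnt$bb), tp$begin),
    flankL = softmaxGroupGrad(c(cnt$nn, cnt$nb), tp$flankL),
    entry  = softmaxGroupGrad(c(cnt$em, cnt$ed), tp$entry),
    match  = matrix(0, k, 3L), insert = matrix(0, k, 2L),
    delete = matrix(0, k, 2L),
    exit   = softmaxGroupGrad(c(cnt$xc, cnt$xe), tp$exit),
    flankR = softmaxGroupGrad(c(cnt$cc, cnt$ce), tp$flankR)
  )
  if (k > 0L) {
    cm <- cbind(cnt$mm, cnt$mi, cnt$md)
    gTrans$match <- cm - tp$match * rowSums(cm)
    ci <- cbind(cnt$im, cnt$ii)
    gTrans$insert <- ci - tp$insert * rowSums(ci)
    cd <- cbind(cnt$dm, cnt$dd)
    gTrans$delete <- cd - tp$delete * rowSums(cd)
  }
  list(logLik = logLik, gMatchLogits = gMatch, gInsertLogits = gIns,
       gTransLogits = gTrans, gammaMatch = gammaMatch)
}

## ---------------------------------------------------------------------------
## Viterbi
## ---------------------------------------------------------------------------

#' Most probable state path for one sequence
#'
#' Log-space Viterbi decoding under the profile topology, with the same
#' optional extra emission term as [forwardLogLik()]. Ties are broken
#' deterministically: match is preferred over delete over insert, and the
#' earlier-listed predecessor wins exact ties, so equal-probability paths
#' decode reproducibly.
#'
#' @param hmm a [ProfileHMM-class].
#' @param seq a residue string (single sequence).
#' @param extraEmission optional list with `match` (`nMatch x L` matrix)
#'   and optionally `insert` (length-`L` vector), as in [forwardLogLik()].
#' @return list with `path`, a data.frame with columns `state` (one of
#'   `"N", "M", "I", "D", "C"`), `index` (match/insert position, `NA` for
#'   flanks) and `seqPos` (1-based emitted residue position, `NA` for
#'   delete states), and `logProb`, the joint log-probability of the path.
#' @export
viterbiDecode <- function(hmm, seq, extraEmission = NULL) {
  validObject(hmm)
  stopifnot(is.character(seq), length(seq) == 1L)
  batch <- encodeSequences(setNames(seq, "s"), hmm@alphabet)
  checkExtra(hmm, batch, extraEmission)
  tl <- transLogTable(hmm)
  codes <- batch@codes[1L, ]
  L <- batch@lengths[1L]; LM <- hmm@nMatch
  emTab <- matchLogProbs(hmm); bgTab <- insertLogProbs(hmm)
  emM <- t(emTab)[codes, , drop = FALSE]      # L x LM
  emBg <- bgTab[codes]                        # L
  if (!is.null(extraEmission)) {
    emM <- emM + t(extraEmission$match[[1L]])
    if (!is.null(extraEmission$insert)) emBg <- emBg + extraEmission$insert[[1L]]
  }
  NEG <- -Inf
  vN <- rep(NEG, L + 1L); vBB <- rep(NEG, L + 1L)
  vC <- rep(NEG, L + 1L); vBE <- rep(NEG, L + 1L)
  vM <- matrix(NEG, LM, L + 1L); vD <- matrix(NEG, LM, L + 1L)
  vI <- matrix(NEG, max(LM - 1L, 1L), L + 1L)
  ## pointers: 1 = from M (or first-listed), 2 = from D, 3 = from I, etc.
  pM <- matrix(NA_integer_, LM, L + 1L); pD <- matrix(NA_integer_, LM, L + 1L)
  pI <- matrix(NA_integer_, max(LM - 1L, 1L), L + 1L)
  pBE <- integer(L + 1L); pC <- integer(L + 1L); pN <- integer(L + 1L)
  pBB <- integer(L + 1L)
  ## j = 0
  vBB[1L] <- tl$bB; pBB[1L] <- 1L            # from B
  vD[1L, 1L] <- vBB[1L] + tl$eD; pD[1L, 1L] <- 4L  # from BB
  if (LM > 1L) for (i in 2:LM) {
    vD[i, 1L] <- vD[i - 1L, 1L] + tl$dd[i - 1L]; pD[i, 1L] <- 2L  # from D
  }
  vBE[1L] <- vD[LM, 1L]; pBE[1L] <- 2L       # from D_LM
  for (j in seq_len(L)) {
    jj <- j + 1L
    ## N: from B (only at j = 1) preferred over N loop
    candB <- (if (j == 1L) 0 else NEG) + tl$bN
    candN <- vN[jj - 1L] + tl$nn
    vN[jj] <- emBg[j] + max(candB, candN)
    pN[jj] <- if (candB >= candN) 1L else 2L
    vBB[jj] <- vN[jj] + tl$nb; pBB[jj] <- 2L   # from N
    ## M states: preference M > D > I among predecessors
    vM[1L, jj] <- emM[j, 1L] + vBB[jj - 1L] + tl$eM
    pM[1L, jj] <- 4L                           # from BB (entry)
    if (LM > 1L) {
      for (i in 2:LM) {
        aM <- vM[i - 1L, jj - 1L] + tl$mm[i - 1L]
        aD <- vD[i - 1L, jj - 1L] + tl$dm[i - 1L]
        aI <- vI[i - 1L, jj - 1L] + tl$im[i - 1L]
        best <- aM; ptr <- 1L
        if (aD > best) { best <- aD; ptr <- 2L }
        if (aI > best) { best <- aI; ptr <- 3L }
        vM[i, jj] <- emM[j, i] + best; pM[i, jj] <- ptr
      }
      for (i in seq_len(LM - 1L)) {
        aM <- vM[i, jj - 1L] + tl$mi[i]
        aI <- vI[i, jj - 1L] + tl$ii[i]
        if (aM >= aI) { vI[i, jj] <- emBg[j] + aM; pI[i, jj] <- 1L }
        else { vI[i, jj] <- emBg[j] + aI; pI[i, jj] <- 3L }
      }
    }
    ## D chain within this j
    vD[1L, jj] <- vBB[jj] + tl$eD; pD[1L, jj] <- 4L
    if (LM > 1L) for (i in 2:LM) {
      aM <- vM[i - 1L, jj] + tl$md[i - 1L]
      aD <- vD[i - 1L, jj] + tl$dd[i - 1L]
      if (aM >= aD) { vD[i, jj] <- aM; pD[i, jj] <- 1L }
      else { vD[i, jj] <- aD; pD[i, jj] <- 2L }
    }
    if (vM[LM, jj] >= vD[LM, jj]) { vBE[jj] <- vM[LM, jj]; pBE[jj] <- 1L }
    else { vBE[jj] <- vD[LM, jj]; pBE[jj] <- 2L }
    aBE <- vBE[jj - 1L] + tl$xc
    aC <- vC[jj - 1L] + tl$cc
    if (aBE >= aC) { vC[jj] <- emBg[j] + aBE; pC[jj] <- 1L }
    else { vC[jj] <- emBg[j] + aC; pC[jj] <- 2L }
  }
  endBE <- vBE[L + 1L] + tl$xe
  endC <- vC[L + 1L] + tl$ce
  logProb <- max(endBE, endC)
  ## traceback
  states <- character(0L); indices <- integer(0L); seqPos <- integer(0L)
  push <- function(st, idx, pos) {
    states <<- c(st, states); indices <<- c(idx, indices)
    seqPos <<- c(pos, seqPos)
  }
  cur <- if (endBE >= endC) "BE" else "Cst"
  i <- LM; j <- L
  while (!(cur == "B")) {
    jj <- j + 1L
    if (cur == "Cst") {
      push("C", NA_integer_, j)
      cur <- if (pC[jj] == 1L) "BE" else "Cst"
      j <- j - 1L
    } else if (cur == "BE") {
      cur <- if (pBE[jj] == 1L) "M" else "D"
      i <- LM
    } else if (cur == "M") {
      push("M", i, j)
      ptr <- pM[i, jj]
      j <- j - 1L
      if (ptr == 4L) { cur <- "BB" }
      else { cur <- c("M", "D", "I")[ptr]; i <- i - 1L }
    } else if (cur == "I") {
      push("I", i, j)
      ptr <- pI[i, jj]
      j <- j - 1L
      cur <- if (ptr == 1L) "M" else "I"
    } else if (cur == "D") {
      push("D", i, NA_integer_)
      ptr <- pD[i, jj]
      if (ptr == 4L) { cur <- "BB" }
      else { cur <- c("M", "D")[ptr]; i <- i - 1L }
    } else if (cur == "BB") {
      cur <- if (pBB[jj] == 1L) "B" else "N"
    } else if (cur == "N") {
      push("N", NA_integer_, j)
      cur <- if (pN[jj] == 1L) "B" else "N"
      j <- j - 1L
    } else stop("internal: unknown state in traceback")
  }
  path <- data.frame(state = states, index = indices, seqPos = seqPos,
                     stringsAsFactors = FALSE)
  if (sum(!is.na(path$seqPos)) != L)
    stop("internal: path emission count mismatch")
  list(path = path, logProb = logProb)
}

## ---------------------------------------------------------------------------
## Amino-acid Dirichlet-mixture prior
## ---------------------------------------------------------------------------

#' Log-density of match emissions under a Dirichlet-mixture prior
#'
#' Sums over match states the log mixture-of-Dirichlet density evaluated
#' at each state's emission distribution; the conventional regularizer for
#' amino-acid profile columns.
#'
#' @param x a [ProfileHMM-class] or an `nStates x A` matrix of emission
#'   distributions (rows on the simplex).
#' @param prior list with `weights` (length `m`, summing to 1) and `alpha`
#'   (`m x A` positive concentration parameters).
#' @return scalar log-density (0 for zero match states).
#' @export
aminoPriorLogDensity <- function(x, prior) {
  p <- if (is(x, "ProfileHMM")) matchEmissions(x) else as.matrix(x)
  if (nrow(p) == 0L) return(0)
  if (abs(sum(prior$weights) - 1) > 1e-8)
    stop("prior weights must sum to 1")
  if (any(prior$alpha <= 0)) stop("concentration parameters must be positive")
  if (any(abs(rowSums(p) - 1) > 1e-6) || any(p < 0))
    stop("emission rows must lie on the probability simplex")
  alpha <- as.matrix(prior$alpha)
  if (ncol(alpha) != ncol(p)) stop("alpha dimension mismatch")
  m <- nrow(alpha)
  logNorm <- lgamma(rowSums(alpha)) - rowSums(lgamma(alpha))
  total <- 0
  logP <- log(pmax(p, PROB_FLOOR))
  for (i in seq_len(nrow(p))) {
    comp <- log(prior$weights) + logNorm +
      as.vector((alpha - 1) %*% logP[i, ])
    total <- total + logsumexp(comp)
  }
  total
}

## Gradient of aminoPriorLogDensity w.r.t. the match emission logits.
aminoPriorGradLogits <- function(hmm, prior) {
  p <- matchEmissions(hmm)
  if (nrow(p) == 0L) return(matrix(0, 0L, ncol(p)))
  alpha <- as.matrix(prior$alpha)
  m <- nrow(alpha)
  logNorm <- lgamma(rowSums(alpha)) - rowSums(lgamma(alpha))
  grad <- matrix(0, nrow(p), ncol(p))
  logP <- log(pmax(p, PROB_FLOOR))
  for (i in seq_len(nrow(p))) {
    comp <- log(prior$weights) + logNorm +
      as.vector((alpha - 1) %*% logP[i, ])
    resp <- exp(comp - logsumexp(comp))
    gp <- as.vector(t(alpha - 1) %*% resp) / pmax(p[i, ], PROB_FLOOR)
    ## chain through the softmax: dz = p * (g - sum(p * g))
    grad[i, ] <- p[i, ] * (gp - sum(p[i, ] * gp))
  }
  grad
}

## ---------------------------------------------------------------------------
## JSON serialization
## ---------------------------------------------------------------------------

#' Serialize a profile HMM to JSON
#'
#' Writes a versioned, human-readable JSON document holding the
#' unconstrained parameters, so a model can be reloaded bit-identically.
#'
#' @param hmm a [ProfileHMM-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfileHMM <- function(hmm, path) {
  validObject(hmm)
  obj <- list(
    schema = paste0("dphmm-profile-", SCHEMA_VERSION),
    nMatch = hmm@nMatch,
    alphabet = paste(hmm@alphabet, collapse = ""),
    matchLogits = hmm@matchLogits,
    insertLogits = hmm@insertLogits,
    transLogits = hmm@transLogits
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a profile HMM from JSON
#'
#' @param path file written by [writeProfileHMM()].
#' @return a [ProfileHMM-class].
#' @export
readProfileHMM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, paste0("dphmm-profile-", SCHEMA_VERSION)))
    stop("unsupported schema: ", obj$schema)
  tl <- obj$transLogits
  k <- as.integer(obj$nMatch) - 1L
  shape <- function(x, ncolumns) {
    v <- as.numeric(unlist(x))
    if (k == 0L || length(v) == 0L) return(matrix(0, 0L, ncolumns))
    matrix(v, nrow = k, ncol = ncolumns, byrow = FALSE)
  }
  new("ProfileHMM",
      nMatch = as.integer(obj$nMatch),
      alphabet = strsplit(obj$alphabet, "", fixed = TRUE)[[1L]],
      matchLogits = matrix(as.numeric(obj$matchLogits),
                           nrow = as.integer(obj$nMatch), byrow = FALSE),
      insertLogits = as.numeric(obj$insertLogits),
      transLogits = list(
        begin = as.numeric(tl$begin), flankL = as.numeric(tl$flankL),
        entry = as.numeric(tl$entry),
        match = shape(tl$match, 3L), insert = shape(tl$insert, 2L),
        delete = shape(tl$delete, 2L),
        exit = as.numeric(tl$exit), flankR = as.numeric(tl$flankR)
      ))
}
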