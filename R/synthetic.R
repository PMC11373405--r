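## Simulators: sampling sequences (with their true state paths) from a
## profile HMM, constructing whole families with controllable conservation
## and indel rate, and an ambiguity construction in which amino acids
## cannot identify the correct columns but planted embeddings can. These
## generators produce every fixture the test suite uses, deterministically
## under a seed.

#' Sample sequences and true state paths from a profile HMM
#'
#' Runs the generative process: transitions are drawn per state, emitting
#' states draw a residue from their emission distribution.
#'
#' @param hmm a [ProfileHMM-class].
#' @param n number of sequences.
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector) and `paths` (list of
#'   data.frames in the format of [viterbiDecode()]).
#' @export
sampleFromHMM <- function(hmm, n, seed = 1L) {
  validObject(hmm)
  tp <- transitionProbs(hmm)
  eMat <- matchEmissions(hmm)
  eBg <- insertEmissions(hmm)
  LM <- hmm@nMatch
  alpha <- hmm@alphabet
  withLocalSeed(childSeed(seed, "sample-hmm"), {
    seqs <- character(n); paths <- vector("list", n)
    for (s in seq_len(n)) {
      chars <- character(0L)
      st <- character(0L); ix <- integer(0L); pos <- integer(0L)
      pick <- function(p) sample.int(length(p), 1L, prob = p)
      emit <- function(p) alpha[pick(p)]
      cur <- "B"; i <- 0L
      repeat {
        if (cur == "B") {
          cur <- if (pick(tp$begin) == 1L) "N" else "BB"
        } else if (cur == "N") {
          chars <- c(chars, emit(eBg))
          st <- c(st, "N"); ix <- c(ix, NA_integer_)
          pos <- c(pos, length(chars))
          cur <- if (pick(tp$flankL) == 1L) "N" else "BB"
        } else if (cur == "BB") {
          if (pick(tp$entry) == 1L) { cur <- "M"; i <- 1L }
          else { cur <- "D"; i <- 1L }
        } else if (cur == "M") {
          chars <- c(chars, emit(eMat[i, ]))
          st <- c(st, "M"); ix <- c(ix, i); pos <- c(pos, length(chars))
          if (i == LM) cur <- "BE"
          else {
            ch <- pick(tp$match[i, ])
            if (ch == 1L) { cur <- "M"; i <- i + 1L }
            else if (ch == 2L) cur <- "I"
            else { cur <- "D"; i <- i + 1L }
          }
        } else if (cur == "I") {
          chars <- c(chars, emit(eBg))
          st <- c(st, "I"); ix <- c(ix, i); pos <- c(pos, length(chars))
          if (pick(tp$insert[i, ]) == 1L) { cur <- "M"; i <- i + 1L }
        } else if (cur == "D") {
          st <- c(st, "D"); ix <- c(ix, i); pos <- c(pos, NA_integer_)
          if (i == LM) cur <- "BE"
          else {
            if (pick(tp$delete[i, ]) == 1L) { cur <- "M"; i <- i + 1L }
            else { cur <- "D"; i <- i + 1L }
          }
        } else if (cur == "BE") {
          cur <- if (pick(tp$exit) == 1L) "Cst" else "End"
        } else if (cur == "Cst") {
          chars <- c(chars, emit(eBg))
          st <- c(st, "C"); ix <- c(ix, NA_integer_)
          pos <- c(pos, length(chars))
          cur <- if (pick(tp$flankR) == 1L) "Cst" else "End"
        } else break
      }
      seqs[s] <- paste(chars, collapse = "")
      paths[[s]] <- data.frame(state = st, index = ix, seqPos = pos,
                               stringsAsFactors = FALSE)
    }
    names(seqs) <- sprintf("seq%04d", seq_len(n))
    names(paths) <- names(seqs)
    ## re-draw on the (rare with sane parameters) event of empty sequences
    empty <- nchar(seqs) == 0L
    if (any(empty)) {
      redo <- sampleFromHMM(hmm, sum(empty), seed = seed + 7919L)
      seqs[empty] <- redo$seqs
      paths[empty] <- redo$paths
    }
    list(seqs = seqs, paths = paths)
  })
}

## true MSA implied by sampled state paths (insertions left-justified)
msaFromPaths <- function(seqs, paths, LM) {
  n <- length(seqs)
  matchChars <- matrix("-", n, LM)
  inserts <- matrix("", n, LM + 1L)
  for (s in seq_len(n)) {
    chars <- strsplit(seqs[[s]], "", fixed = TRUE)[[1L]]
    p <- paths[[s]]
    for (k in seq_len(nrow(p))) {
      st <- p$state[k]; i <- p$index[k]; pos <- p$seqPos[k]
      if (st == "M") matchChars[s, i] <- toupper(chars[pos])
      else if (st == "I") inserts[s, i + 1L] <-
          paste0(inserts[s, i + 1L], tolower(chars[pos]))
      else if (st == "N") inserts[s, 1L] <-
          paste0(inserts[s, 1L], tolower(chars[pos]))
      else if (st == "C") inserts[s, LM + 1L] <-
          paste0(inserts[s, LM + 1L], tolower(chars[pos]))
    }
  }
  assembleMSA(names(seqs), matchChars, inserts)
}

#' Simulate a protein family with known ground truth
#'
#' Builds a random peaked profile HMM, samples `n` sequences from it, and
#' returns the true alignment implied by the sampled state paths. Match
#' emission distributions are drawn from a symmetric Dirichlet with
#' concentration `1/conservation` (larger conservation gives more peaked
#' columns; `Inf` gives one-hot emissions); all indel and flank
#' probabilities equal `indelRate` (geometric indel lengths), so
#' `indelRate = 0` gives gap-free alignments. The first ten sequences form
#' the designated reference subset, mirroring the reference/homolog split
#' of curated benchmark families.
#'
#' @param LM number of match states.
#' @param n number of sequences.
#' @param conservation peakedness of the match emissions (`> 0`, may be
#'   `Inf`).
#' @param indelRate probability of opening/extending indels and flanks, in
#'   `[0, 0.5)`.
#' @param seed RNG seed.
#' @return list with `hmm`, `seqs`, `msa` (the true [ProfileMSA-class]),
#'   `paths`, and `refIds` (identifiers of the reference subset).
#' @export
makeFamily <- function(LM, n, conservation = 5, indelRate = 0.02,
                       seed = 1L) {
  stopifnot(LM >= 1, n >= 1, conservation > 0,
            indelRate >= 0, indelRate < 0.5)
  A <- length(AA_LETTERS)
  matchP <- withLocalSeed(childSeed(seed, "family-profile"), {
    if (is.infinite(conservation)) {
      hot <- sample.int(A, LM, replace = TRUE)
      m <- matrix(PROB_FLOOR, LM, A)
      m[cbind(seq_len(LM), hot)] <- 1
      m / rowSums(m)
    } else {
      conc <- 1 / conservation
      m <- matrix(stats::rgamma(LM * A, shape = conc), LM, A)
      ## guard against all-zero rows at extreme peakedness
      m[rowSums(m) == 0, ] <- 1 / A
      m / rowSums(m)
    }
  })
  p <- max(indelRate, 1e-12)
  lg <- function(x) log(pmax(x, 1e-12))
  k <- max(LM - 1L, 0L)
  tl <- list(
    begin  = lg(c(p, 1 - p)),
    flankL = lg(c(p, 1 - p)),
    entry  = lg(c(1 - p, p)),
    match  = matrix(rep(lg(c(1 - 2 * p, p, p)), each = k), k, 3L),
    insert = matrix(rep(lg(c(1 - p, p)), each = k), k, 2L),
    delete = matrix(rep(lg(c(1 - p, p)), each = k), k, 2L),
    exit   = lg(c(p, 1 - p)),
    flankR = lg(c(p, 1 - p))
  )
  hmm <- makeProfileHMM(LM, matchLogits = log(pmax(matchP, PROB_FLOOR)),
                        insertLogits = rep(0, A), transLogits = tl)
  sam <- sampleFromHMM(hmm, n, seed = childSeed(seed, "family-sample"))
  msa <- msaFromPaths(sam$seqs, sam$paths, LM)
  list(hmm = hmm, seqs = sam$seqs, msa = msa, paths = sam$paths,
       refIds = head(names(sam$seqs), 10L))
}

#' Simulate an alignment-ambiguous family with disambiguating embeddings
#'
#' Two equally sized subfamilies occupy disjoint halves of a `2k`-column
#' alignment: subfamily A aligns to columns `1..k` and subfamily B to
#' columns `k+1..2k`, but column `j` of the A block and column `k+j` of
#' the B block share the same amino-acid distribution, so the residues
#' alone carry no evidence about which block a sequence belongs to. Each
#' true column additionally has a planted latent embedding direction;
#' per-residue embeddings are that direction plus unit Gaussian noise, so
#' column identity is recoverable from the embeddings exactly when
#' `signalStrength > 0`.
#'
#' @param k columns per block (the true alignment has `2k` columns and
#'   every sequence has length `k`).
#' @param n number of sequences (alternating subfamily labels).
#' @param r embedding dimension of the planted (compressed) embeddings.
#' @param signalStrength scale of the planted column directions; 0 makes
#'   the embeddings uninformative.
#' @param conservation peakedness of the shared column distributions.
#' @param seed RNG seed.
#' @return list with `seqs`, `msa` (the true 2k-column alignment),
#'   `cache` (named list of `k x r` planted embedding matrices, a drop-in
#'   compressed-embedding cache), `labels`, and `refIds` (the first ten
#'   sequences).
#' @export
makeAmbiguousFamily <- function(k = 5L, n = 100L, r = 16L,
                                signalStrength = 2, conservation = 8,
                                seed = 1L) {
  stopifnot(k >= 1, n >= 2, r >= 1, signalStrength >= 0)
  A <- length(AA_LETTERS)
  withLocalSeed(childSeed(seed, "ambiguous-family"), {
    conc <- 1 / conservation
    colDist <- matrix(stats::rgamma(k * A, shape = conc), k, A)
    colDist[rowSums(colDist) == 0, ] <- 1 / A
    colDist <- colDist / rowSums(colDist)
    ## one latent direction per true column (2k columns)
    dirs <- matrix(rnorm(2L * k * r), 2L * k, r)
    dirs <- dirs / sqrt(rowSums(dirs^2)) * signalStrength
    labels <- rep(c("A", "B"), length.out = n)
    ids <- sprintf("seq%04d", seq_len(n))
    seqs <- character(n)
    rows <- character(n)
    cache <- vector("list", n)
    for (s in seq_len(n)) {
      res <- vapply(seq_len(k), function(j)
        AA_LETTERS[sample.int(A, 1L, prob = colDist[j, ])], character(1L))
      seqs[s] <- paste(res, collapse = "")
      rows[s] <- if (labels[s] == "A")
        paste0(seqs[s], strrep("-", k)) else paste0(strrep("-", k), seqs[s])
      colOffset <- if (labels[s] == "A") 0L else k
      emb <- dirs[colOffset + seq_len(k), , drop = FALSE] +
        matrix(rnorm(k * r), k, r)
      cache[[s]] <- emb
    }
    names(seqs) <- ids; names(cache) <- ids
    msa <- new("ProfileMSA", ids = ids, rows = rows,
               isMatch = rep(TRUE, 2L * k))
    list(seqs = seqs, msa = msa, cache = cache, labels = labels,
         refIds = head(ids, 10L))
  })
}

#' Simulate residue-pair training data with a planted low-rank signal
#'
#' Fixture for scoring-model pretraining: aligned residue pairs share a
#' latent vector living in a fixed `latentDim`-dimensional subspace of the
#' `d`-dimensional embedding space (the premise of low-rank scoring:
#' alignment-relevant signal concentrates in few directions), while
#' unaligned residues have independent latents. Both sides add isotropic
#' Gaussian noise.
#'
#' @param nPairs number of sequence pairs.
#' @param L residues per sequence (the induced alignment is the identity).
#' @param d embedding dimension.
#' @param latentDim dimension of the shared-signal subspace.
#' @param noise noise standard deviation per coordinate.
#' @param seed RNG seed for the latents/noise; the subspace basis is keyed
#'   by `basisSeed` so train and held-out sets share it.
#' @param basisSeed seed of the fixed subspace basis.
#' @return list of items with `embS`, `embT` (`L x d`) and `pairs`
#'   (the identity alignment, 0-based), ready for
#'   [pretrainScoringModel()].
#' @export
makePlantedPairs <- function(nPairs, L = 10L, d = 32L, latentDim = 12L,
                             noise = 0.5, seed = 1L, basisSeed = 87654L) {
  B <- withLocalSeed(basisSeed,
                     matrix(rnorm(latentDim * d, sd = 1 / sqrt(latentDim)),
                            latentDim, d))
  withLocalSeed(childSeed(seed, "planted-pairs"), {
    lapply(seq_len(nPairs), function(i) {
      z <- matrix(rnorm(L * latentDim), L, latentDim) %*% B
      list(embS = z + noise * matrix(rnorm(L * d), L, d),
           embT = z + noise * matrix(rnorm(L * d), L, d),
           pairs = cbind(0:(L - 1L), 0:(L - 1L)))
    })
  })
}
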