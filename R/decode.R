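## Decoding a multiple alignment from a trained model: every sequence (and
## its compressed embeddings, when the model uses them) is aligned to the
## profile by Viterbi; match-state emissions define the match columns,
## insert/flank emissions fill left-justified lowercase insert blocks.

#' Decode a multiple alignment from a trained model
#'
#' Runs Viterbi decoding for every sequence (adding the tempered embedding
#' emission term when the model was trained with embeddings) and assembles
#' the alignment: residues emitted at match state `M_i` go to match column
#' `i` (uppercase; delete states leave `-`), and residues emitted at
#' insert or flank states go to insert blocks between match columns,
#' left-justified and lowercase. De-gapping any row reproduces its input
#' sequence.
#'
#' @param model a [TrainedProfile-class].
#' @param seqs named character vector of residue strings.
#' @param cache compressed-embedding cache; required iff the model was
#'   trained with embeddings.
#' @return a [ProfileMSA-class]; rows in input order.
#' @export
decodeMSA <- function(model, seqs, cache = NULL) {
  stopifnot(is(model, "TrainedProfile"))
  hmm <- model@hmm
  ems <- model@emissions
  entries <- NULL
  if (!is.null(ems)) {
    if (is.null(cache)) stop("model uses embeddings but no cache was given")
    entries <- cacheEntries(cache, names(seqs))
  }
  LM <- hmm@nMatch
  n <- length(seqs)
  matchChars <- matrix("-", n, LM)
  inserts <- matrix("", n, LM + 1L)  # blocks: before M_1, after M_i, i=1..LM
  for (s in seq_len(n)) {
    extra <- NULL
    if (!is.null(ems)) {
      g <- embeddingEmissionGrid(ems, entries[[s]])
      extra <- list(match = list(g$match), insert = list(g$insert))
    }
    vit <- viterbiDecode(hmm, seqs[[s]], extra)
    chars <- strsplit(seqs[[s]], "", fixed = TRUE)[[1L]]
    for (k in seq_len(nrow(vit$path))) {
      st <- vit$path$state[k]; i <- vit$path$index[k]
      pos <- vit$path$seqPos[k]
      if (st == "M") {
        matchChars[s, i] <- toupper(chars[pos])
      } else if (st == "I") {
        inserts[s, i + 1L] <- paste0(inserts[s, i + 1L], tolower(chars[pos]))
      } else if (st == "N") {
        inserts[s, 1L] <- paste0(inserts[s, 1L], tolower(chars[pos]))
      } else if (st == "C") {
        inserts[s, LM + 1L] <- paste0(inserts[s, LM + 1L], tolower(chars[pos]))
      }
    }
  }
  assembleMSA(names(seqs), matchChars, inserts)
}

## build a ProfileMSA from per-sequence match characters and insert blocks
assembleMSA <- function(ids, matchChars, inserts) {
  n <- nrow(matchChars); LM <- ncol(matchChars)
  blockWidth <- apply(nchar(inserts), 2L, max)
  rows <- character(n)
  isMatch <- logical(0L)
  for (b in seq_len(LM + 1L)) {
    if (b <= LM) {
      isMatch <- c(isMatch, rep(FALSE, blockWidth[b]), TRUE)
    } else {
      isMatch <- c(isMatch, rep(FALSE, blockWidth[b]))
    }
  }
  for (s in seq_len(n)) {
    parts <- character(0L)
    for (b in seq_len(LM + 1L)) {
      if (blockWidth[b] > 0L) {
        ins <- inserts[s, b]
        pad <- strrep("-", blockWidth[b] - nchar(ins))
        parts <- c(parts, paste0(ins, pad))  # left-justified
      }
      if (b <= LM) parts <- c(parts, matchChars[s, b])
    }
    rows[s] <- paste(parts, collapse = "")
  }
  new("ProfileMSA", ids = ids, rows = rows, isMatch = isMatch)
}

#' Restrict an alignment to a reference subset
#'
#' Keeps the rows with the given identifiers (in the given order) and
#' drops columns that become all-gap; the standard preparation before
#' scoring a decoded alignment against a gold-standard reference subset.
#'
#' @param msa a [ProfileMSA-class].
#' @param ids identifiers of the reference rows.
#' @return a [ProfileMSA-class].
#' @export
extractReferenceSubalignment <- function(msa, ids) {
  unknown <- setdiff(ids, msa@ids)
  if (length(unknown))
    stop("unknown identifier(s): ", paste(unknown, collapse = ", "))
  sel <- match(ids, msa@ids)
  mat <- msaMatrix(msa)[sel, , drop = FALSE]
  isGap <- mat == "-" | mat == "."
  keep <- colSums(!isGap) > 0L
  mat <- mat[, keep, drop = FALSE]
  rows <- apply(mat, 1L, paste, collapse = "")
  if (length(ids) == 1L) rows <- paste(mat[1L, ], collapse = "")
  new("ProfileMSA", ids = ids, rows = as.character(rows),
      isMatch = msa@isMatch[keep])
}

#' Per-residue match-state posterior table
#'
#' Probabilistic alternative to the single Viterbi alignment: for every
#' residue, the forward-backward posterior probability of each match
#' state, plus the total probability of being in any insert/flank state.
#'
#' @param model a [TrainedProfile-class].
#' @param seqs named character vector of residue strings.
#' @param cache compressed-embedding cache, iff the model uses embeddings.
#' @param topK report the `topK` most probable match states per residue.
#' @return data.frame with columns `id`, `pos`, `residue`, `state` (match
#'   index or `0` for the aggregated insert/flank probability) and
#'   `posterior`.
#' @export
matchPosteriors <- function(model, seqs, cache = NULL, topK = 3L) {
  hmm <- model@hmm; ems <- model@emissions
  batch <- encodeSequences(seqs, hmm@alphabet)
  extra <- NULL
  if (!is.null(ems)) {
    if (is.null(cache)) stop("model uses embeddings but no cache was given")
    entries <- cacheEntries(cache, names(seqs))
    extra <- extraFromCache(ems, entries)
  }
  fb <- forwardBackwardGrad(hmm, batch, extra)
  out <- list()
  for (s in seq_along(seqs)) {
    g <- fb$gammaMatch[[s]]               # LM x L posteriors
    chars <- strsplit(seqs[[s]], "", fixed = TRUE)[[1L]]
    for (j in seq_len(ncol(g))) {
      insertP <- max(0, 1 - sum(g[, j]))
      k <- order(g[, j], decreasing = TRUE)[seq_len(min(topK, nrow(g)))]
      out[[length(out) + 1L]] <- data.frame(
        id = names(seqs)[s], pos = j, residue = chars[j],
        state = c(k, 0L), posterior = c(g[k, j], insertP))
    }
  }
  do.call(rbind, out)
}
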