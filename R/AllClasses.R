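#' @import methods
NULL

## ---------------------------------------------------------------------------
## ProfileHMM
## ---------------------------------------------------------------------------

#' Profile hidden Markov model with unconstrained parameters
#'
#' The classic profile topology: a chain of match states `M_1..M_L` with
#' per-position insert states `I_1..I_{L-1}` and silent delete states
#' `D_1..D_L`, framed by a left flanking insert state, a right flanking
#' insert state, and silent begin/end states. Entry is through `M_1`/`D_1`
#' and exit through `M_L`/`D_L` (glocal alignment); insert-to-delete and
#' delete-to-insert transitions are excluded.
#'
#' All parameters are stored unconstrained; transition distributions are
#' obtained by a per-state softmax and emission distributions by a per-row
#' softmax, so the model can be trained by unconstrained gradient ascent.
#' Insert and both flanking states share a single emission distribution.
#'
#' @slot nMatch number of match states (model length).
#' @slot alphabet residue alphabet; the 20 amino acids by default. The
#'   unknown residue `X` is handled outside the alphabet and emitted with a
#'   fixed uniform-background probability at every emitting state.
#' @slot matchLogits `nMatch x A` matrix of unconstrained match emission
#'   parameters (softmax rows give the emission distributions).
#' @slot insertLogits length-`A` unconstrained shared insert/flank emission
#'   parameters.
#' @slot transLogits named list of unconstrained transition parameter
#'   groups: `begin` (to left flank / to body), `flankL` (self loop / to
#'   body), `entry` (to `M_1` / to `D_1`), `match` (`(L-1) x 3`: to next
#'   match / to insert / to next delete), `insert` (`(L-1) x 2`: to next
#'   match / self loop), `delete` (`(L-1) x 2`: to next match / to next
#'   delete), `exit` (to right flank / to end), `flankR` (self loop / to
#'   end).
#'
#' @seealso [makeProfileHMM()], [forwardLogLik()], [viterbiDecode()]
#' @export
setClass("ProfileHMM",
  representation(
    nMatch = "integer",
    alphabet = "character",
    matchLogits = "matrix",
    insertLogits = "numeric",
    transLogits = "list"
  )
)

setValidity("ProfileHMM", function(object) {
  msg <- character()
  L <- object@nMatch
  A <- length(object@alphabet)
  if (L < 1L) msg <- c(msg, "nMatch must be >= 1")
  if (A < 2L) msg <- c(msg, "alphabet must have >= 2 letters")
  if (!identical(dim(object@matchLogits), c(L, A)))
    msg <- c(msg, "matchLogits must be nMatch x |alphabet|")
  if (length(object@insertLogits) != A)
    msg <- c(msg, "insertLogits must have one entry per alphabet letter")
  tl <- object@transLogits
  need <- c("begin", "flankL", "entry", "match", "insert", "delete",
            "exit", "flankR")
  if (!all(need %in% names(tl))) {
    msg <- c(msg, paste("transLogits must contain:",
                        paste(need, collapse = ", ")))
  } else {
    for (nm in c("begin", "flankL", "entry", "exit", "flankR"))
      if (length(tl[[nm]]) != 2L)
        msg <- c(msg, paste0("transLogits$", nm, " must have length 2"))
    if (!identical(dim(tl$match), c(L - 1L, 3L)))
      msg <- c(msg, "transLogits$match must be (nMatch-1) x 3")
    if (!identical(dim(tl$insert), c(L - 1L, 2L)))
      msg <- c(msg, "transLogits$insert must be (nMatch-1) x 2")
    if (!identical(dim(tl$delete), c(L - 1L, 2L)))
      msg <- c(msg, "transLogits$delete must be (nMatch-1) x 2")
  }
  allPar <- c(object@matchLogits, object@insertLogits,
              unlist(object@transLogits))
  if (!all(is.finite(allPar))) msg <- c(msg, "parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileHMM-class number of match states
#' @param x,object a `ProfileHMM`
#' @export
setGeneric("nMatch", function(x) standardGeneric("nMatch"))

#' @rdname ProfileHMM-class
#' @export
setMethod("nMatch", "ProfileHMM", function(x) x@nMatch)

#' Match-state emission distributions
#'
#' @param x a [ProfileHMM-class] object.
#' @return `nMatch x A` stochastic matrix (rows sum to 1).
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @rdname matchEmissions
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) {
  p <- rowSoftmax(x@matchLogits)
  dimnames(p) <- list(NULL, x@alphabet)
  p
})

#' Shared insert/flank emission distribution
#'
#' @param x a [ProfileHMM-class] object.
#' @return length-`A` probability vector.
#' @export
setGeneric("insertEmissions", function(x) standardGeneric("insertEmissions"))

#' @rdname insertEmissions
#' @export
setMethod("insertEmissions", "ProfileHMM", function(x) {
  setNames(softmax(x@insertLogits), x@alphabet)
})

#' Transition probabilities of a profile HMM
#'
#' @param x a [ProfileHMM-class] object.
#' @return named list of per-state transition distributions, mirroring the
#'   `transLogits` groups of [ProfileHMM-class]; each row/vector sums to 1.
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname transitionProbs
#' @export
setMethod("transitionProbs", "ProfileHMM", function(x) {
  tl <- x@transLogits
  out <- list(
    begin  = setNames(softmax(tl$begin), c("flankL", "body")),
    flankL = setNames(softmax(tl$flankL), c("loop", "body")),
    entry  = setNames(softmax(tl$entry), c("M1", "D1")),
    exit   = setNames(softmax(tl$exit), c("flankR", "end")),
    flankR = setNames(softmax(tl$flankR), c("loop", "end"))
  )
  L <- x@nMatch
  if (L > 1L) {
    out$match <- rowSoftmax(tl$match)
    colnames(out$match) <- c("toM", "toI", "toD")
    out$insert <- rowSoftmax(tl$insert)
    colnames(out$insert) <- c("toM", "loop")
    out$delete <- rowSoftmax(tl$delete)
    colnames(out$delete) <- c("toM", "toD")
  } else {
    out$match <- matrix(0, 0L, 3L, dimnames = list(NULL, c("toM", "toI", "toD")))
    out$insert <- matrix(0, 0L, 2L, dimnames = list(NULL, c("toM", "loop")))
    out$delete <- matrix(0, 0L, 2L, dimnames = list(NULL, c("toM", "toD")))
  }
  out
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM with", object@nMatch, "match states over a",
      length(object@alphabet), "letter alphabet\n")
  p <- matchEmissions(object)
  peak <- apply(p, 1L, max)
  cat("  match emission peakedness (max prob): ",
      sprintf("%.2f", mean(peak)), " (mean)\n", sep = "")
})

## ---------------------------------------------------------------------------
## EmbeddingEmissions
## ---------------------------------------------------------------------------

#' Diagonal-Gaussian embedding emissions at match states
#'
#' Each match state `M_i` emits a compressed `r`-dimensional embedding
#' vector under a diagonal Gaussian `N(mu_i, diag(var_i))`. The joint
#' emission of a residue and its embedding is
#' `P(residue | q) * P(embedding | q)^tau`, so the temperature `tau`
#' regulates the relative influence of the embeddings. Insert and flank
#' states use a single frozen background Gaussian obtained by
#' moment-matching the embedding prior.
#'
#' Scales are stored unconstrained (`var = floor + softplus(scaleRaw)`)
#' so they stay positive under gradient ascent.
#'
#' @slot mean `nMatch x r` matrix of Gaussian means.
#' @slot scaleRaw `nMatch x r` matrix of unconstrained scale parameters.
#' @slot tau non-negative temperature.
#' @slot bgMean,bgVar length-`r` background (insert/flank) Gaussian
#'   parameters, frozen during training.
#' @export
setClass("EmbeddingEmissions",
  representation(
    mean = "matrix",
    scaleRaw = "matrix",
    tau = "numeric",
    bgMean = "numeric",
    bgVar = "numeric"
  )
)

setValidity("EmbeddingEmissions", function(object) {
  msg <- character()
  if (!identical(dim(object@mean), dim(object@scaleRaw)))
    msg <- c(msg, "mean and scaleRaw must have identical dimensions")
  r <- ncol(object@mean)
  if (length(object@bgMean) != r || length(object@bgVar) != r)
    msg <- c(msg, "background parameters must have length r")
  if (length(object@tau) != 1L || object@tau < 0)
    msg <- c(msg, "tau must be a single non-negative number")
  if (any(object@bgVar < VAR_FLOOR))
    msg <- c(msg, "background variances below the variance floor")
  if (length(msg)) msg else TRUE
})

#' Embedding variances implied by the unconstrained scales
#'
#' @param x an [EmbeddingEmissions-class] object.
#' @return `nMatch x r` matrix of variances, all `>=` the variance floor.
#' @export
setGeneric("embeddingVars", function(x) standardGeneric("embeddingVars"))

#' @rdname embeddingVars
#' @export
setMethod("embeddingVars", "EmbeddingEmissions", function(x) {
  VAR_FLOOR + softplus(x@scaleRaw)
})

setMethod("show", "EmbeddingEmissions", function(object) {
  cat("EmbeddingEmissions: ", nrow(object@mean), " match states, r = ",
      ncol(object@mean), ", tau = ", object@tau, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EmbeddingPrior
## ---------------------------------------------------------------------------

#' Mixture-of-Gaussians prior over match-state embedding means
#'
#' A `C`-component diagonal-Gaussian mixture fitted to embeddings of
#' residues found in densely populated alignment columns. During training
#' it acts as a log-density penalty on the match-state means so that they
#' resemble embeddings the embedder actually produces.
#'
#' @slot weights length-`C` mixture weights (simplex).
#' @slot mean `C x r` component means.
#' @slot var `C x r` positive component variances (diagonal covariances).
#' @export
setClass("EmbeddingPrior",
  representation(weights = "numeric", mean = "matrix", var = "matrix")
)

setValidity("EmbeddingPrior", function(object) {
  msg <- character()
  C <- length(object@weights)
  if (C < 1L) msg <- c(msg, "at least one component required")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "mixture weights must sum to 1")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (nrow(object@mean) != C || nrow(object@var) != C)
    msg <- c(msg, "mean and var must have one row per component")
  if (!identical(dim(object@mean), dim(object@var)))
    msg <- c(msg, "mean and var must have identical dimensions")
  if (any(object@var <= 0)) msg <- c(msg, "variances must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EmbeddingPrior", function(object) {
  cat("EmbeddingPrior: ", length(object@weights), " components, r = ",
      ncol(object@mean), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ScoringModel
## ---------------------------------------------------------------------------

#' Low-rank bilinear residue-pair scoring model
#'
#' Scores a pair of residue embeddings `x, y` (rows of the `L x d`
#' embedding matrices of two sequences) with the symmetric bilinear form
#' `x' W y`, where `W = R R'` is constrained to rank `r << d` by the factor
#' `R` (`d x r`). The logistic sigmoid of the score matrix is interpreted
#' as the probability that the two residues align. The same factor defines
#' the compression map `emb %*% R` used to reduce embeddings to `r`
#' dimensions before profile training.
#'
#' @slot R `d x r` factor matrix; `W = R R'` is symmetric PSD by
#'   construction.
#' @slot activation activation name; fixed to `"logistic-sigmoid"`.
#' @export
setClass("ScoringModel",
  representation(R = "matrix", activation = "character")
)

setValidity("ScoringModel", function(object) {
  msg <- character()
  d <- nrow(object@R); r <- ncol(object@R)
  if (d < 1L || r < 1L) msg <- c(msg, "R must be a non-empty d x r matrix")
  if (r >= d) msg <- c(msg, "low-rank requirement: r must be < d")
  if (!identical(object@activation, "logistic-sigmoid"))
    msg <- c(msg, "activation must be 'logistic-sigmoid'")
  if (!all(is.finite(object@R))) msg <- c(msg, "R must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoringModel", function(object) {
  cat("ScoringModel: d = ", nrow(object@R), ", r = ", ncol(object@R),
      " (", parameterCount(object), " trainable parameters)\n", sep = "")
})

## ---------------------------------------------------------------------------
## ProfileMSA
## ---------------------------------------------------------------------------

#' Multiple sequence alignment with match-column annotation
#'
#' Rows are equal-length gapped strings. Match columns carry uppercase
#' residues and `-` gaps; insert columns carry lowercase residues and are
#' padded with `-` (aligned FASTA) or `.` (A2M). De-gapping any row
#' reproduces the corresponding input sequence exactly.
#'
#' @slot ids row identifiers.
#' @slot rows gapped row strings, all of the same width.
#' @slot isMatch logical flag per column: `TRUE` for match columns.
#' @export
setClass("ProfileMSA",
  representation(ids = "character", rows = "character", isMatch = "logical")
)

setValidity("ProfileMSA", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@rows))
    msg <- c(msg, "ids and rows must have equal length")
  if (length(object@rows) == 0L) msg <- c(msg, "alignment must be non-empty")
  w <- unique(nchar(object@rows))
  if (length(w) > 1L) msg <- c(msg, "rows must all have the same width")
  if (length(w) == 1L && length(object@isMatch) != w)
    msg <- c(msg, "isMatch must have one flag per column")
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate row identifiers")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileMSA-class alignment width (number of columns)
#' @param x,object a `ProfileMSA`
#' @export
setMethod("ncol", "ProfileMSA", function(x) {
  if (length(x@rows)) nchar(x@rows[[1L]]) else 0L
})

#' @describeIn ProfileMSA-class number of rows
#' @export
setMethod("nrow", "ProfileMSA", function(x) length(x@rows))

#' Row identifiers of an alignment
#' @param x a [ProfileMSA-class] object.
#' @export
setGeneric("msaIds", function(x) standardGeneric("msaIds"))

#' @rdname msaIds
#' @export
setMethod("msaIds", "ProfileMSA", function(x) x@ids)

#' Gapped row strings of an alignment
#' @param x a [ProfileMSA-class] object.
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname msaRows
#' @export
setMethod("msaRows", "ProfileMSA", function(x) setNames(x@rows, x@ids))

#' Match-column flags of an alignment
#' @param x a [ProfileMSA-class] object.
#' @export
setGeneric("matchColumns", function(x) standardGeneric("matchColumns"))

#' @rdname matchColumns
#' @export
setMethod("matchColumns", "ProfileMSA", function(x) x@isMatch)

setMethod("show", "ProfileMSA", function(object) {
  cat("ProfileMSA: ", length(object@rows), " rows x ", ncol(object),
      " columns (", sum(object@isMatch), " match columns)\n", sep = "")
  n <- min(5L, length(object@rows))
  for (i in seq_len(n)) {
    row <- object@rows[[i]]
    if (nchar(row) > 60) row <- paste0(substr(row, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", substr(object@ids[[i]], 1, 12), row))
  }
  if (length(object@rows) > n) cat("  ...\n")
})

#' Construct a ProfileMSA
#'
#' @param ids row identifiers.
#' @param rows equal-width gapped strings (gap `-`; `.` is accepted as an
#'   insert-column gap and normalized on read).
#' @param isMatch logical per-column match flags; by default columns
#'   containing any lowercase residue or `.` are treated as insert columns
#'   and all others as match columns.
#' @return a [ProfileMSA-class] object.
#' @export
ProfileMSA <- function(ids, rows, isMatch = NULL) {
  ids <- as.character(ids)
  rows <- as.character(rows)
  if (is.null(isMatch)) {
    if (length(rows) == 0L) stop("alignment must be non-empty")
    chars <- strsplit(rows, "", fixed = TRUE)
    w <- unique(lengths(chars))
    if (length(w) != 1L) stop("rows must all have the same width")
    mat <- do.call(rbind, chars)
    isMatch <- apply(mat, 2L, function(col)
      !any(col == "." | (col %in% letters)))
  }
  new("ProfileMSA", ids = ids, rows = rows, isMatch = as.logical(isMatch))
}

## ---------------------------------------------------------------------------
## TrainedProfile
## ---------------------------------------------------------------------------

#' A fitted deep profile HMM replica
#'
#' Bundles the profile HMM, the embedding emission model (absent when the
#' model was trained on amino acids only), the per-epoch objective trace,
#' the training configuration and the replica seed.
#'
#' @slot hmm the fitted [ProfileHMM-class].
#' @slot emissions an [EmbeddingEmissions-class] or `NULL`.
#' @slot trace numeric per-epoch objective values.
#' @slot config the training configuration list.
#' @slot seed the replica seed.
#' @export
setClass("TrainedProfile",
  representation(hmm = "ProfileHMM", emissions = "ANY", trace = "numeric",
                 config = "list", seed = "integer")
)

setMethod("show", "TrainedProfile", function(object) {
  cat("TrainedProfile (seed ", object@seed, "): ", object@hmm@nMatch,
      " match states, ", length(object@trace), " epochs, final objective ",
      sprintf("%.4f", tail(object@trace, 1L)), "\n", sep = "")
})

#' Final objective value of a trained replica
#' @param x a [TrainedProfile-class] object.
#' @export
setGeneric("finalObjective", function(x) standardGeneric("finalObjective"))

#' @rdname finalObjective
#' @export
setMethod("finalObjective", "TrainedProfile", function(x) {
  as.numeric(tail(x@trace, 1L))
})
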