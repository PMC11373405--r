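## Reference-based alignment accuracy: sum-of-pairs (SP), total column
## (TC) and weighted column scores. Matching is by residue coordinates
## (row id, ungapped residue index), never by characters, so duplicated
## residues are unambiguous.

## For each row, the column index of each residue (ungapped coordinates),
## after checking that pred and ref hold the same sequences.
alignmentCoordinates <- function(msa) {
  mat <- msaMatrix(msa)
  isGap <- mat == "-" | mat == "."
  lapply(seq_len(nrow(mat)), function(a) which(!isGap[a, ]))
}

checkComparable <- function(pred, ref) {
  if (!setequal(pred@ids, ref@ids))
    stop("prediction and reference contain different sequence sets")
  sp <- ungappedSequences(pred); sr <- ungappedSequences(ref)
  bad <- names(sr)[sp[names(sr)] != sr]
  if (length(bad))
    stop("sequence content differs after de-gapping for: ",
         paste(bad, collapse = ", "))
  invisible(NULL)
}

## column labels: for every (row, column) the residue index, NA at gaps
residueIndexMatrix <- function(msa) {
  mat <- msaMatrix(msa)
  isGap <- mat == "-" | mat == "."
  idx <- matrix(NA_integer_, nrow(mat), ncol(mat))
  for (a in seq_len(nrow(mat))) idx[a, !isGap[a, ]] <- seq_len(sum(!isGap[a, ]))
  rownames(idx) <- msa@ids
  idx
}

## set of aligned residue pairs as strings "rowA:i|rowB:j" with rowA < rowB
alignedPairKeys <- function(msa) {
  idx <- residueIndexMatrix(msa)
  ids <- msa@ids
  ord <- order(ids)
  keys <- character(0L)
  n <- length(ids)
  for (aa in seq_len(n - 1L)) {
    for (bb in seq.int(aa + 1L, n)) {
      a <- ord[aa]; b <- ord[bb]
      both <- !is.na(idx[a, ]) & !is.na(idx[b, ])
      if (any(both)) {
        keys <- c(keys, paste0(ids[a], ":", idx[a, both], "|",
                               ids[b], ":", idx[b, both]))
      }
    }
  }
  keys
}

#' Sum-of-pairs score
#'
#' Percentage of residue pairs aligned in the reference (two residues
#' sharing a column in which neither row has a gap) that are also aligned
#' in the prediction.
#'
#' @param pred,ref [ProfileMSA-class] objects over the same sequences
#'   (matched by id; each row must de-gap to the same sequence in both).
#' @return percentage in `[0, 100]`.
#' @export
spScore <- function(pred, ref) {
  checkComparable(pred, ref)
  refPairs <- alignedPairKeys(ref)
  if (length(refPairs) == 0L) return(0)
  predPairs <- alignedPairKeys(pred)
  100 * sum(refPairs %in% predPairs) / length(refPairs)
}

## per-column residue coordinate sets, as canonical strings
columnKeys <- function(msa) {
  idx <- residueIndexMatrix(msa)
  ids <- msa@ids
  ord <- order(ids)
  apply(idx[ord, , drop = FALSE], 2L, function(col) {
    filled <- !is.na(col)
    paste(ids[ord][filled], col[filled], sep = ":", collapse = "|")
  })
}

#' Total column score
#'
#' Percentage of reference columns whose exact residue-coordinate set
#' appears as a column of the prediction. Columns are compared as sets of
#' (row id, residue index) over non-gap entries; all-gap reference columns
#' are ignored.
#'
#' @inheritParams spScore
#' @return percentage in `[0, 100]`.
#' @export
tcScore <- function(pred, ref) {
  checkComparable(pred, ref)
  refCols <- columnKeys(ref)
  refCols <- refCols[refCols != ""]
  if (length(refCols) == 0L) stop("reference has no non-empty columns")
  predCols <- columnKeys(pred)
  100 * sum(refCols %in% predCols) / length(refCols)
}

#' Weighted column score
#'
#' Total column score with each reference column weighted by its share of
#' residue pairs: `w_c = pairs(c) / sum_c' pairs(c')` with
#' `pairs(c) = m (m - 1) / 2` for `m` non-gap residues in the column, so
#' dense columns count more and sparse columns are forgiven.
#'
#' @inheritParams spScore
#' @return percentage in `[0, 100]`.
#' @export
columnScore <- function(pred, ref) {
  checkComparable(pred, ref)
  idx <- residueIndexMatrix(ref)
  m <- colSums(!is.na(idx))
  pairs <- m * (m - 1) / 2
  if (sum(pairs) == 0) stop("reference has no residue pairs to weight by")
  refCols <- columnKeys(ref)
  predCols <- columnKeys(pred)
  matched <- refCols %in% predCols & refCols != ""
  100 * sum(pairs[matched]) / sum(pairs)
}

#' Score a prediction against a reference
#'
#' @inheritParams spScore
#' @return data.frame with columns `sp`, `tc`, `column`.
#' @export
evaluateAlignment <- function(pred, ref) {
  data.frame(sp = spScore(pred, ref), tc = tcScore(pred, ref),
             column = columnScore(pred, ref))
}
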