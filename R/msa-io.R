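## Sequence and alignment I/O. Plain FASTA goes through Biostrings; the
## mixed-case A2M dialect is written/read directly because XStringSet does
## not carry case information.

#' Read unaligned protein sequences from a FASTA file
#'
#' Residues are uppercased; the non-standard codes `B, Z, J, U, O` and the
#' placeholder `*`/`.` are mapped to the unknown residue `X` (a terminal
#' `*` stop symbol is stripped first). `X` is emitted under a uniform
#' background distribution by all models in this package, which keeps the
#' 20-symbol emission simplex clean.
#'
#' @param path FASTA file.
#' @return a named character vector of residue strings (names are the
#'   record identifiers, the first whitespace-delimited token of each
#'   header), in file order.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifiers: ", paste(dup, collapse = ", "))
  seqs <- normalizeResidues(as.character(set))
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop("zero-length record(s): ", paste(empty, collapse = ", "))
  setNames(seqs, ids)
}

## uppercase, strip terminal '*', collapse non-standard letters to 'X'
normalizeResidues <- function(x) {
  x <- toupper(x)
  x <- sub("\\*$", "", x)
  gsub(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), "X", x)
}

#' Write a multiple alignment
#'
#' @param msa a [ProfileMSA-class] object.
#' @param path output file.
#' @param dialect `"aligned-fasta"` writes every column uppercase with `-`
#'   gaps; `"a2m"` writes match columns uppercase with `-` gaps and insert
#'   columns lowercase with `.` padding.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(msa, path, dialect = c("aligned-fasta", "a2m")) {
  dialect <- match.arg(dialect)
  stopifnot(is(msa, "ProfileMSA"))
  validObject(msa)
  mat <- msaMatrix(msa)
  isMatch <- msa@isMatch
  lines <- character(0L)
  for (i in seq_along(msa@ids)) {
    row <- mat[i, ]
    if (dialect == "aligned-fasta") {
      row <- toupper(row)
      row[row == "."] <- "-"
    } else {
      orig <- row
      row[isMatch] <- toupper(orig[isMatch])
      row[isMatch & orig %in% c("-", ".")] <- "-"
      row[!isMatch] <- tolower(orig[!isMatch])
      row[!isMatch & orig %in% c("-", ".")] <- "."
    }
    lines <- c(lines, paste0(">", msa@ids[i]), paste(row, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a multiple alignment
#'
#' Accepts both dialects written by [writeAlignment()]. For aligned FASTA
#' (all uppercase) the match-column flags are inferred as the columns with
#' `<= 50%` gaps when `inferMatch = TRUE`, otherwise every column is a
#' match column. For A2M the case/`.` annotation determines the flags.
#'
#' @param path alignment file.
#' @param inferMatch for the aligned FASTA dialect, infer match columns
#'   from gap density (default `FALSE`).
#' @return a [ProfileMSA-class] object.
#' @export
readAlignment <- function(path, inferMatch = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifiers: ", paste(dup, collapse = ", "))
  rows <- as.character(set)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows have unequal lengths")
  a2m <- any(grepl("[a-z.]", rows))
  if (a2m) {
    msa <- ProfileMSA(ids, rows)   # flags from case/dot annotation
  } else {
    w <- nchar(rows[[1L]])
    isMatch <- rep(TRUE, w)
    if (inferMatch) {
      mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
      gapFrac <- colMeans(mat == "-")
      isMatch <- gapFrac <= 0.5
      for (i in seq_along(rows)) {
        chars <- mat[i, ]
        chars[!isMatch] <- tolower(chars[!isMatch])
        rows[i] <- paste(chars, collapse = "")
      }
    }
    msa <- new("ProfileMSA", ids = ids, rows = rows, isMatch = isMatch)
  }
  validObject(msa)
  msa
}

## character matrix view of an alignment (rows x columns)
msaMatrix <- function(msa) {
  do.call(rbind, strsplit(msa@rows, "", fixed = TRUE))
}

#' Recover the ungapped sequences of an alignment
#'
#' @param msa a [ProfileMSA-class] object.
#' @return named character vector of uppercase ungapped sequences.
#' @export
ungappedSequences <- function(msa) {
  setNames(toupper(gsub("[-.]", "", msa@rows)), msa@ids)
}

#' Induce pairwise alignments from a multiple alignment
#'
#' For every unordered pair of rows, extracts the residue index pairs
#' `(i, j)` (0-based, in ungapped coordinates) that share an alignment
#' column in which neither row has a gap. These induced pairwise
#' alignments supervise scoring-model pretraining.
#'
#' @param msa a [ProfileMSA-class] object.
#' @return list of pairwise alignments, each a list with elements `idA`,
#'   `idB` and `pairs` (a `k x 2` integer matrix, strictly increasing in
#'   both columns). Fewer than two rows give an empty list.
#' @export
inducePairwiseAlignments <- function(msa) {
  stopifnot(is(msa, "ProfileMSA"))
  n <- length(msa@rows)
  if (n < 2L) return(list())
  mat <- msaMatrix(msa)
  isGap <- mat == "-" | mat == "."
  # residue index (0-based) of each non-gap cell
  resIdx <- t(apply(isGap, 1L, function(g) cumsum(!g) - 1L))
  out <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      shared <- !isGap[a, ] & !isGap[b, ]
      pairs <- cbind(i = resIdx[a, shared], j = resIdx[b, shared])
      k <- k + 1L
      out[[k]] <- list(idA = msa@ids[a], idB = msa@ids[b],
                       pairs = matrix(as.integer(pairs), ncol = 2L,
                                      dimnames = list(NULL, c("i", "j"))))
    }
  }
  out
}
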