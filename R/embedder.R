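## Pluggable per-residue embedding providers. The package ships a
## deterministic synthetic embedder that maps each residue's local sequence
## window to a pseudo-random unit-variance vector, so equal contexts give
## equal embeddings and any context change moves the vector; real protein
## language models can be plugged in through the registry without touching
## the rest of the pipeline.

.embedderRegistry <- new.env(parent = emptyenv())
.embedCounter <- new.env(parent = emptyenv())
.embedCounter$calls <- 0L

#' Register an embedding provider
#'
#' The registration hook for plugging in real protein language models: a
#' provider is a function `function(seq, spec)` returning an `L x d`
#' matrix, deterministic for a fixed `(sequence, spec)` with row `j`
#' depending on the context of position `j`.
#'
#' @param name provider name used in [embedderSpec()].
#' @param fun provider function.
#' @return `name`, invisibly.
#' @export
registerEmbedder <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .embedderRegistry)
  invisible(name)
}

#' List registered embedders
#' @return character vector of provider names.
#' @export
listEmbedders <- function() sort(ls(.embedderRegistry))

#' Describe an embedder configuration
#'
#' @param name registered provider name (default the synthetic embedder).
#' @param d embedding dimension.
#' @param window odd context window width (synthetic embedder only).
#' @param seed seed folded into the synthetic embedder's hashing.
#' @return an `EmbedderSpec` (plain list with class attribute).
#' @export
embedderSpec <- function(name = "synthetic", d = 32L, window = 3L,
                         seed = 1L) {
  if (d < 1L) stop("embedding dimension must be >= 1")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd positive")
  structure(list(name = name, d = as.integer(d), window = as.integer(window),
                 seed = as.integer(seed)),
            class = "EmbedderSpec")
}

#' Embed one sequence
#'
#' @param seq residue string.
#' @param spec an [embedderSpec()].
#' @return `L x d` embedding matrix.
#' @export
embedSequence <- function(seq, spec) {
  fun <- get0(spec$name, envir = .embedderRegistry)
  if (is.null(fun))
    stop("unknown embedder '", spec$name, "'; registered embedders: ",
         paste(listEmbedders(), collapse = ", "))
  .embedCounter$calls <- .embedCounter$calls + 1L
  fun(seq, spec)
}

## Deterministic synthetic embedder: each position's vector is drawn from
## an RNG seeded by a hash of the window string centered at the position
## (edge-padded with '^'/'$'), so the embedding is context-sensitive and
## reproducible without any model weights. Window vectors are memoized.
.syntheticWindowCache <- new.env(parent = emptyenv())

syntheticEmbedder <- function(seq, spec) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  half <- (spec$window - 1L) %/% 2L
  padded <- c(rep("^", half), chars, rep("$", half))
  out <- matrix(0, L, spec$d)
  for (j in seq_len(L)) {
    win <- paste(padded[j:(j + spec$window - 1L)], collapse = "")
    key <- paste0(spec$seed, ":", spec$d, ":", win)
    vec <- get0(key, envir = .syntheticWindowCache)
    if (is.null(vec)) {
      vec <- withLocalSeed(stringHash31(key), rnorm(spec$d))
      assign(key, vec, envir = .syntheticWindowCache)
    }
    out[j, ] <- vec
  }
  out
}

#' Current value of the embedding call counter
#'
#' Counts calls to [embedSequence()]; used to verify that the compressed
#' cache is not recomputed when its provenance matches.
#' @return integer count.
#' @export
embedCallCount <- function() .embedCounter$calls

## provenance tag combining embedder spec and scoring-model content
cacheProvenance <- function(spec, model) {
  list(embedder = spec$name, d = spec$d, window = spec$window,
       seed = spec$seed, r = ncol(model@R),
       scoringHash = numericHash(model@R))
}

#' Precompute and cache compressed embeddings
#'
#' Computes `compressEmbeddings(embedSequence(s))` for every sequence and
#' stores the result, keyed by identifier, together with a JSON provenance
#' sidecar recording the embedder spec and a content hash of the scoring
#' model. A re-run with matching provenance loads the cache instead of
#' recomputing; a provenance mismatch is refused unless `overwrite = TRUE`.
#'
#' @param seqs named character vector of residue strings.
#' @param spec an [embedderSpec()].
#' @param model a [ScoringModel-class] whose `d` matches the embedder.
#' @param cachePath optional file path (an `.rds` container; a `.json`
#'   sidecar is written next to it). `NULL` keeps the cache in memory only.
#' @param overwrite replace a cache whose provenance does not match.
#' @return an `EmbeddingCache`: list with `entries` (named list of `L x r`
#'   matrices) and `provenance`.
#' @export
precomputeCompressed <- function(seqs, spec, model, cachePath = NULL,
                                 overwrite = FALSE) {
  if (spec$d != nrow(model@R))
    stop("embedder dimension (", spec$d, ") does not match scoring model d (",
         nrow(model@R), ")")
  prov <- cacheProvenance(spec, model)
  if (!is.null(cachePath) && file.exists(cachePath)) {
    sidecar <- paste0(cachePath, ".json")
    oldProv <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
    if (identical(lapply(oldProv, as.character), lapply(prov, as.character))) {
      cached <- readRDS(cachePath)
      if (all(names(seqs) %in% names(cached)))
        return(structure(list(entries = cached[names(seqs)],
                              provenance = prov), class = "EmbeddingCache"))
    } else if (!overwrite) {
      stop("existing cache at ", cachePath, " has different provenance; ",
           "pass overwrite = TRUE to replace it")
    }
  }
  entries <- lapply(seqs, function(s)
    compressEmbeddings(embedSequence(s, spec), model))
  names(entries) <- names(seqs)
  for (id in names(entries)) {
    if (nrow(entries[[id]]) != nchar(seqs[[id]]))
      stop("cache row count mismatch for ", id)
  }
  if (!is.null(cachePath)) {
    saveRDS(entries, cachePath)
    jsonlite::write_json(prov, paste0(cachePath, ".json"), auto_unbox = TRUE,
                         digits = I(17))
  }
  structure(list(entries = entries, provenance = prov),
            class = "EmbeddingCache")
}

#' @export
print.EmbeddingCache <- function(x, ...) {
  r <- if (length(x$entries)) ncol(x$entries[[1L]]) else NA_integer_
  cat("EmbeddingCache:", length(x$entries), "sequences, r =", r, "\n")
  invisible(x)
}
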