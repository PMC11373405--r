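## Unsupervised fitting of the (deep) profile HMM: batch gradient ascent
## with Adam on the likelihood-plus-priors objective, several
## independently seeded replicas, and best-replica selection. Gradients of
## the forward log-likelihood come from the backward pass (posterior
## expected counts); Gaussian embedding-parameter gradients are driven by
## the match-state emission posteriors.

#' Training configuration
#'
#' @param useEmbeddings train the joint amino-acid/embedding model (needs
#'   a compressed-embedding cache).
#' @param frozenInsertions keep insert/flank emission parameters fixed
#'   (default on). The insert/flank embedding background density is frozen
#'   always; this flag additionally freezes the shared insert amino-acid
#'   distribution.
#' @param tau embedding temperature.
#' @param batchSize minibatch size (sequences).
#' @param lrHMM,lrEmb Adam learning rates for HMM parameters and for the
#'   Gaussian embedding parameters.
#' @param maxEpochs,patience epoch cap and early-stopping patience on the
#'   objective plateau.
#' @param parallel number of independently seeded model replicas.
#' @param seed master seed; all replica seeds derive from it.
#' @param lengthOverride model length; `NULL` uses the median sequence
#'   length.
#' @param maxLenFactor sequences longer than this multiple of the median
#'   length are rejected with an error.
#' @param priorComponents mixture components for an embedding prior fitted
#'   on the fly (when `embeddingPrior` is `NULL`).
#' @param embeddingPrior optional [EmbeddingPrior-class] to use directly.
#' @param aminoPrior optional Dirichlet-mixture prior (list with `weights`
#'   and `alpha`); `NULL` means a flat prior.
#' @return a `TrainingConfig` list.
#' @export
trainingConfig <- function(useEmbeddings = FALSE, frozenInsertions = TRUE,
                           tau = 1, batchSize = 256L, lrHMM = 0.05,
                           lrEmb = 0.05, maxEpochs = 200L, patience = 10L,
                           parallel = 4L, seed = 1L, lengthOverride = NULL,
                           maxLenFactor = 10, priorComponents = 32L,
                           embeddingPrior = NULL, aminoPrior = NULL) {
  stopifnot(tau >= 0, batchSize >= 1, lrHMM > 0, lrEmb > 0, maxEpochs >= 1,
            patience >= 1, parallel >= 1, maxLenFactor > 0)
  structure(list(useEmbeddings = useEmbeddings,
                 frozenInsertions = frozenInsertions, tau = tau,
                 batchSize = as.integer(batchSize), lrHMM = lrHMM,
                 lrEmb = lrEmb, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 parallel = as.integer(parallel), seed = as.integer(seed),
                 lengthOverride = lengthOverride, maxLenFactor = maxLenFactor,
                 priorComponents = as.integer(priorComponents),
                 embeddingPrior = embeddingPrior, aminoPrior = aminoPrior),
            class = "TrainingConfig")
}

## normalize a cache argument to a named list of L x r matrices
cacheEntries <- function(cache, ids) {
  entries <- if (inherits(cache, "EmbeddingCache")) cache$entries else cache
  missing <- setdiff(ids, names(entries))
  if (length(missing))
    stop("missing cache entries for: ", paste(missing, collapse = ", "))
  entries[ids]
}

## per-sequence extra emission terms from the Gaussian model + cache
extraFromCache <- function(ems, entries) {
  grids <- lapply(entries, function(m) embeddingEmissionGrid(ems, m))
  list(match = lapply(grids, `[[`, "match"),
       insert = lapply(grids, `[[`, "insert"))
}

#' Training objective
#'
#' Mean per-sequence forward log-likelihood (with the tempered embedding
#' emission term when an embedding model is supplied) plus the amino-acid
#' prior and embedding prior log-densities, each scaled by `1/n`.
#'
#' @param hmm a [ProfileHMM-class].
#' @param ems an [EmbeddingEmissions-class] or `NULL` (amino acids only).
#' @param batch an [EncodedBatch-class] or named character vector.
#' @param cache compressed-embedding cache ([precomputeCompressed()]) or
#'   named list of `L x r` matrices; required iff `ems` is given.
#' @param aminoPrior optional Dirichlet-mixture prior list.
#' @param embeddingPrior optional [EmbeddingPrior-class].
#' @return scalar objective value.
#' @export
objective <- function(hmm, ems = NULL, batch, cache = NULL,
                      aminoPrior = NULL, embeddingPrior = NULL) {
  if (is.character(batch)) batch <- encodeSequences(batch, hmm@alphabet)
  n <- nrow(batch@codes)
  extra <- NULL
  if (!is.null(ems)) {
    if (is.null(cache)) stop("embedding model given but no cache")
    entries <- cacheEntries(cache, batch@ids)
    extra <- extraFromCache(ems, entries)
  }
  obj <- mean(forwardLogLik(hmm, batch, extra))
  if (!is.null(aminoPrior))
    obj <- obj + aminoPriorLogDensity(hmm, aminoPrior) / n
  if (!is.null(ems) && !is.null(embeddingPrior))
    obj <- obj + priorLogDensity(ems, embeddingPrior) / n
  obj
}

## Gaussian embedding parameter gradients from match-state posteriors.
## gammas/comp are per-sequence lists; returns gradients w.r.t. mean and
## the unconstrained scaleRaw.
gaussianGradFromGammas <- function(ems, gammas, comp) {
  mu <- ems@mean; vars <- embeddingVars(ems); tau <- ems@tau
  gMean <- mu * 0; gVar <- mu * 0
  wtot <- numeric(nrow(mu))
  S1 <- mu * 0; S2 <- mu * 0
  for (s in seq_along(gammas)) {
    g <- gammas[[s]]              # LM x L
    x <- comp[[s]]                # L x r
    S1 <- S1 + g %*% x
    S2 <- S2 + g %*% (x * x)
    wtot <- wtot + rowSums(g)
  }
  gMean <- tau * (S1 - wtot * mu) / vars
  quad <- S2 - 2 * mu * S1 + wtot * mu^2
  gVar <- tau * 0.5 * (quad / vars^2 - wtot / vars)
  list(mean = gMean, scaleRaw = gVar * sigmoid(ems@scaleRaw))
}

#' Fit deep profile HMM replicas by gradient ascent
#'
#' Trains `config$parallel` independently seeded replicas with Adam on
#' shuffled minibatches, maximizing [objective()]. With
#' `config$useEmbeddings` the match states jointly emit residues and
#' compressed embeddings; the insert/flank embedding density stays frozen,
#' and with `config$frozenInsertions` (the default) the shared insert
#' amino-acid distribution receives no updates either. Deterministic given
#' `config$seed`.
#'
#' @param seqs named character vector of at least two residue strings.
#' @param cache compressed-embedding cache; required iff
#'   `config$useEmbeddings`.
#' @param config a [trainingConfig()].
#' @return list of [TrainedProfile-class] replicas.
#' @export
fitProfiles <- function(seqs, cache = NULL, config = trainingConfig()) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  lens <- nchar(seqs)
  med <- stats::median(lens)
  tooLong <- lens > config$maxLenFactor * med
  if (any(tooLong))
    stop("sequence(s) longer than ", config$maxLenFactor,
         "x the median length: ",
         paste(names(seqs)[tooLong], collapse = ", "))
  if (length(unique(seqs)) == 1L && nchar(seqs[[1L]]) == 1L)
    warning("degenerate family: all inputs are one identical residue")
  LM <- if (!is.null(config$lengthOverride))
    as.integer(config$lengthOverride) else as.integer(round(med))
  LM <- max(LM, 1L)
  batch <- encodeSequences(seqs)
  n <- length(seqs)
  entries <- NULL; embPrior <- NULL
  if (config$useEmbeddings) {
    if (is.null(cache)) stop("useEmbeddings is on but no cache was given")
    entries <- cacheEntries(cache, batch@ids)
    embPrior <- config$embeddingPrior
    if (is.null(embPrior)) {
      vecs <- do.call(rbind, entries)
      if (nrow(vecs) > 5000L) {
        keep <- withLocalSeed(childSeed(config$seed, "prior-subsample"),
                              sample.int(nrow(vecs), 5000L))
        vecs <- vecs[keep, , drop = FALSE]
      }
      C <- min(config$priorComponents, max(1L, nrow(vecs) %/% 2L))
      embPrior <- fitEmbeddingPrior(vecs, C,
                                    seed = childSeed(config$seed, "prior"))
    }
  }
  lapply(seq_len(config$parallel), function(rep) {
    repSeed <- childSeed(config$seed, paste0("replica", rep))
    trainReplica(batch, entries, embPrior, LM, config, repSeed)
  })
}

trainReplica <- function(batch, entries, embPrior, LM, config, repSeed) {
  n <- nrow(batch@codes)
  hmm <- makeProfileHMM(LM, seed = repSeed)
  ems <- NULL
  if (config$useEmbeddings)
    ems <- initEmissionsFromPrior(embPrior, LM, seed = repSeed,
                                  tau = config$tau)
  par <- hmmToParList(hmm, ems)
  lr <- list(default = config$lrHMM,
             emsMean = config$lrEmb, emsScale = config$lrEmb)
  opt <- adamInit(par)
  trace <- numeric(0L)
  best <- -Inf; bestPar <- par; sinceBest <- 0L; bestEpoch <- 0L
  withLocalSeed(childSeed(repSeed, "epochs"), {
    for (ep in seq_len(config$maxEpochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / config$batchSize)
      for (b in seq_len(nb)) {
        idx <- ord[seq.int((b - 1L) * config$batchSize + 1L,
                           min(b * config$batchSize, n))]
        grad <- batchGradient(par, batch, idx, entries, embPrior, config, n)
        step <- adamStep(opt, par, grad, lr, maximize = TRUE)
        opt <- step$state
        par <- step$par
      }
      mods <- parListToModels(par, config)
      obj <- epochObjective(mods$hmm, mods$ems, batch, entries, embPrior,
                            config)
      trace <- c(trace, obj)
      if (isTRUE(getOption("dpHMM.verbose")))
        message("[dphmm] replica ", repSeed, " epoch ", ep,
                " objective ", sprintf("%.4f", obj))
      if (!is.finite(best) || obj > best + 1e-4 * (abs(best) + 1e-8)) {
        best <- obj; bestPar <- par; sinceBest <- 0L; bestEpoch <- ep
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  })
  ## the returned parameters are those of the best epoch; truncate the
  ## trace accordingly so the final trace value matches the model
  trace <- trace[seq_len(max(bestEpoch, 1L))]
  mods <- parListToModels(bestPar, config)
  new("TrainedProfile", hmm = mods$hmm, emissions = mods$ems, trace = trace,
      config = unclass(config)[setdiff(names(config), "embeddingPrior")],
      seed = as.integer(repSeed))
}

## flat parameter list <-> model objects; the flat list is what Adam sees.
hmmToParList <- function(hmm, ems) {
  par <- list(matchLogits = hmm@matchLogits,
              insertLogits = hmm@insertLogits)
  for (nm in names(hmm@transLogits))
    par[[paste0("trans.", nm)]] <- hmm@transLogits[[nm]]
  attr(par, "nMatch") <- hmm@nMatch
  attr(par, "alphabet") <- hmm@alphabet
  if (!is.null(ems)) {
    par$emsMean <- ems@mean
    par$emsScale <- ems@scaleRaw
    attr(par, "emsTau") <- ems@tau
    attr(par, "emsBgMean") <- ems@bgMean
    attr(par, "emsBgVar") <- ems@bgVar
  }
  par
}

parListToModels <- function(par, config) {
  transNames <- sub("^trans\\.", "", grep("^trans\\.", names(par),
                                          value = TRUE))
  tl <- setNames(lapply(transNames, function(nm) par[[paste0("trans.", nm)]]),
                 transNames)
  hmm <- new("ProfileHMM", nMatch = attr(par, "nMatch"),
             alphabet = attr(par, "alphabet"),
             matchLogits = par$matchLogits,
             insertLogits = par$insertLogits, transLogits = tl)
  ems <- NULL
  if (!is.null(par$emsMean)) {
    ems <- new("EmbeddingEmissions", mean = par$emsMean,
               scaleRaw = par$emsScale, tau = attr(par, "emsTau"),
               bgMean = attr(par, "emsBgMean"), bgVar = attr(par, "emsBgVar"))
  }
  list(hmm = hmm, ems = ems)
}

## gradient of the objective for one minibatch (mean log-likelihood over
## the batch + priors scaled by 1/n)
batchGradient <- function(par, batch, idx, entries, embPrior, config, n) {
  mods <- parListToModels(par, config)
  hmm <- mods$hmm; ems <- mods$ems
  sub <- new("EncodedBatch",
             codes = batch@codes[idx, , drop = FALSE],
             lengths = batch@lengths[idx], ids = batch@ids[idx])
  extra <- NULL; subEntries <- NULL
  if (!is.null(ems)) {
    subEntries <- entries[idx]
    extra <- extraFromCache(ems, subEntries)
  }
  fb <- forwardBackwardGrad(hmm, sub, extra)
  B <- length(idx)
  grad <- list(matchLogits = fb$gMatchLogits / B,
               insertLogits = if (config$frozenInsertions) NULL
                              else fb$gInsertLogits / B)
  for (nm in names(fb$gTransLogits))
    grad[[paste0("trans.", nm)]] <- fb$gTransLogits[[nm]] / B
  if (!is.null(config$aminoPrior)) {
    grad$matchLogits <- grad$matchLogits +
      aminoPriorGradLogits(hmm, config$aminoPrior) / n
  }
  if (!is.null(ems)) {
    gg <- gaussianGradFromGammas(ems, fb$gammaMatch, subEntries)
    grad$emsMean <- gg$mean / B
    grad$emsScale <- gg$scaleRaw / B
    if (!is.null(embPrior))
      grad$emsMean <- grad$emsMean + priorGradMeans(ems, embPrior) / n
  }
  grad
}

epochObjective <- function(hmm, ems, batch, entries, embPrior, config) {
  extra <- if (!is.null(ems)) extraFromCache(ems, entries) else NULL
  obj <- mean(forwardLogLik(hmm, batch, extra))
  n <- nrow(batch@codes)
  if (!is.null(config$aminoPrior))
    obj <- obj + aminoPriorLogDensity(hmm, config$aminoPrior) / n
  if (!is.null(ems) && !is.null(embPrior))
    obj <- obj + priorLogDensity(ems, embPrior) / n
  obj
}

#' Select the best replica
#'
#' The replica with the highest final objective; exact ties go to the
#' smallest replica seed.
#'
#' @param models list of [TrainedProfile-class] objects.
#' @return a single [TrainedProfile-class].
#' @export
selectBest <- function(models) {
  if (length(models) == 0L) stop("no models to select from")
  objs <- vapply(models, finalObjective, numeric(1L))
  seeds <- vapply(models, function(m) m@seed, integer(1L))
  best <- which(objs == max(objs))
  models[[best[which.min(seeds[best])]]]
}

#' Write a trained replica checkpoint
#'
#' Profile JSON plus (when present) an embedding-emission JSON, the config
#' and the objective trace, in one JSON document.
#'
#' @param model a [TrainedProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrainedProfile <- function(model, path) {
  ems <- NULL
  if (!is.null(model@emissions)) {
    e <- model@emissions
    ems <- list(mean = e@mean, scaleRaw = e@scaleRaw, tau = e@tau,
                bgMean = e@bgMean, bgVar = e@bgVar)
  }
  cfg <- model@config
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  jsonlite::write_json(list(
    schema = paste0("dphmm-trained-", SCHEMA_VERSION),
    hmm = list(nMatch = model@hmm@nMatch,
               alphabet = paste(model@hmm@alphabet, collapse = ""),
               matchLogits = model@hmm@matchLogits,
               insertLogits = model@hmm@insertLogits,
               transLogits = model@hmm@transLogits),
    emissions = ems, trace = model@trace, config = cfg, seed = model@seed
  ), path, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
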