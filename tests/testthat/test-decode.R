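trainedToy <- function(seed = 13) {
  fam <- makeFamily(LM = 6, n = 150, conservation = 6, indelRate = 0.03,
                    seed = seed)
  cfg <- trainingConfig(maxEpochs = 120, parallel = 2, seed = 3,
                        lengthOverride = 6)
  list(fam = fam, model = selectBest(fitProfiles(fam$seqs, config = cfg)))
}

test_that("decoding round-trips sequences and recovers known paths", {
  tt <- trainedToy()
  msa <- decodeMSA(tt$model, tt$fam$seqs)
  # de-gapping every row reproduces the input exactly
  expect_identical(unname(ungappedSequences(msa)), unname(tt$fam$seqs))
  expect_identical(msaIds(msa), names(tt$fam$seqs))
  # column count >= number of match states minus all-delete columns
  expect_gte(ncol(msa), sum(matchColumns(msa)))
  expect_gte(sum(matchColumns(msa)), 1L)
  # a model trained from scratch on a modest family aligns most residue
  # pairs of the reference subset correctly (full-scale parameter recovery
  # is exercised in the acceptance suite)
  ref <- extractReferenceSubalignment(tt$fam$msa, tt$fam$refIds)
  pred <- extractReferenceSubalignment(msa, tt$fam$refIds)
  expect_gte(spScore(pred, ref), 85)
})

test_that("decoding the true model reproduces true paths for most residues", {
  fam <- makeFamily(LM = 8, n = 50, conservation = 12, indelRate = 0.02,
                    seed = 99)
  model <- new("TrainedProfile", hmm = fam$hmm, emissions = NULL,
               trace = 0, config = list(), seed = 1L)
  msa <- decodeMSA(model, fam$seqs)
  # per-residue match-state agreement with the recorded true paths
  agree <- 0; total <- 0
  for (s in seq_along(fam$seqs)) {
    truth <- fam$paths[[s]]
    vit <- viterbiDecode(fam$hmm, fam$seqs[[s]])
    tm <- truth[truth$state == "M", ]
    vm <- vit$path[vit$path$state == "M", ]
    total <- total + nrow(tm)
    agree <- agree + sum(paste(tm$index, tm$seqPos) %in%
                           paste(vm$index, vm$seqPos))
  }
  expect_gte(agree / total, 0.95)
})

test_that("single and duplicated sequences decode trivially", {
  fam <- makeFamily(LM = 4, n = 30, conservation = 10, indelRate = 0,
                    seed = 7)
  model <- new("TrainedProfile", hmm = fam$hmm, emissions = NULL,
               trace = 0, config = list(), seed = 1L)
  one <- decodeMSA(model, fam$seqs[1])
  expect_identical(unname(ungappedSequences(one)), unname(fam$seqs[1]))
  two <- decodeMSA(model, setNames(rep(fam$seqs[[1]], 2), c("a", "b")))
  rows <- msaRows(two)
  expect_identical(unname(rows[1]), unname(rows[2]))
})

test_that("reference subalignment extraction drops all-gap columns", {
  msa <- ProfileMSA(c("r1", "r2", "r3"), c("AC-E", "A-DE", "AC-E"),
                    isMatch = rep(TRUE, 4))
  # extracting everything changes nothing
  all3 <- extractReferenceSubalignment(msa, c("r1", "r2", "r3"))
  expect_identical(msaRows(all3), msaRows(msa))
  # r1 + r3 leave column 3 (only r2's D) all-gap: it must disappear
  sub <- extractReferenceSubalignment(msa, c("r1", "r3"))
  expect_identical(unname(msaRows(sub)), c("ACE", "ACE"))
  # one row collapses to the ungapped sequence
  one <- extractReferenceSubalignment(msa, "r2")
  expect_identical(unname(msaRows(one)), "ADE")
  expect_error(extractReferenceSubalignment(msa, "nope"), "unknown")
})

test_that("match posteriors are proper distributions consistent with decoding", {
  tt <- trainedToy(17)
  post <- matchPosteriors(tt$model, tt$fam$seqs[1:5], topK = 6)
  expect_true(all(post$posterior >= -1e-9 & post$posterior <= 1 + 1e-9))
  # per residue, the reported top-K plus insert mass is <= 1
  sums <- tapply(post$posterior, paste(post$id, post$pos), sum)
  expect_true(all(sums <= 1 + 1e-6))
})
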