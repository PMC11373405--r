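---
title: "Deep profile HMM alignment: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep profile HMM alignment: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpHMM)
```

## The model

A profile hidden Markov model (pHMM) describes a protein family with a
chain of *match* states `M_1..M_L` — position-specific amino-acid
distributions corresponding to conserved alignment columns — interleaved
with *insert* states (unaligned residues between columns) and silent
*delete* states (skipped columns), framed by left/right flanking insert
states and silent begin/end states. The marginal probability of an
unaligned sequence `S` sums over all state paths `pi`:

    P(S) = sum_pi prod_j P(pi_j | pi_{j-1}) P(S_j | pi_j)

computed by the forward algorithm. `dpHMM` trains this model on
*unaligned* sequences by gradient ascent on the likelihood plus priors,
then decodes the multiple alignment by aligning every sequence to the
fitted profile with the Viterbi algorithm: residues emitted at `M_i` form
match column `i`, insert-state residues form lowercase, left-justified
insert blocks.

The *deep* extension attaches to every match state a diagonal Gaussian
over compressed per-residue embedding vectors. Under conditional
independence and a temperature `tau`, the joint emission of a residue and
its embedding `phi(S)_j` is

    P(S_j, phi(S)_j | q) = P(S_j | q) * P(phi(S)_j | q)^tau

so in log space the embedding log-density simply adds to the amino-acid
emission term, weighted by `tau`. Because embeddings are
context-sensitive, two residues with the same amino acid but different
structural or biochemical context can be told apart — evidence a
residue-only profile cannot express.

Three companion components make this workable:

* **Scoring model / compressor.** Raw embeddings are high-dimensional
  (`d` up to thousands). A factor `R` (`d x r`, `r << d`) defines a
  symmetric positive-semidefinite bilinear form `W = R R'`. In training
  mode, `sigmoid(phi(S) R (phi(T) R)')` is the matrix of residue-pair
  alignment probabilities, pretrained with weighted binary cross-entropy
  on pairwise alignments induced from reference MSAs (only `R` receives
  gradients). In inference mode the same `R` compresses embeddings to
  `r` dimensions; by construction the compressed inner products reproduce
  the scores exactly, so profile training never touches raw embeddings.
* **Embedding prior.** A `C`-component diagonal-Gaussian mixture fitted
  by EM to embeddings of residues from densely populated alignment
  columns. It initializes match-state means (sampled from the mixture)
  and acts as a log-density penalty on them during training, keeping
  states near realistic embedding space.
* **Insert/flank embedding background.** Insert and flank states share a
  single frozen Gaussian obtained by moment-matching the prior mixture
  (mixture mean; within- plus between-component variance). Only match
  states have trainable embedding distributions.

## Gradients without autodiff

The training loop is plain batch gradient ascent with Adam, but the
gradients of the forward log-likelihood are computed analytically rather
than by automatic differentiation: the backward pass yields posterior
expected transition and emission counts, and the derivative of `log P(S)`
with respect to an unconstrained softmax parameter is the classic
"observed minus expected" form `E[count] - p * E[group total]`. Gaussian
mean and scale gradients are driven by the match-state emission
posteriors (the derivative of the log-likelihood with respect to the
per-state, per-position extra emission term *is* that posterior). Every
gradient path is verified against central finite differences in the test
suite. Scales are parameterized as `variance = 1e-6 + softplus(raw)` so
positivity survives gradient steps; all dynamic programming is done in
log space with log-sum-exp and a probability floor of `1e-16` before any
logarithm.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tau` | 1.0 | embedding temperature in the joint emission; 0 recovers the residue-only model. A learned temperature is deliberately out of scope for determinism. |
| `r` | 16 | compressed embedding dimension / rank of the scoring factor. Small ranks lose little accuracy while being much cheaper. |
| `C` (`priorComponents`) | 32 | mixture components of the embedding prior (clamped to half the available vectors on small inputs). |
| model length | median input length | number of match states; scale-free default, overridable. |
| `lrHMM`, `lrEmb` | 0.05, 0.05 | Adam learning rates. Equal rates matter: with a much smaller embedding rate the Gaussian means cannot leave the neighbourhood of their prior draw before the transition structure hardens, and training collapses to residue-only optima (we observed exactly this on the ambiguity benchmark below). |
| `batchSize` | 256 | sequences per gradient step. |
| `maxEpochs`, `patience` | 200, 10 | epoch cap and early stopping on an objective plateau (relative tolerance `1e-4`). |
| `parallel` | 4 | independently seeded replicas; the replica with the best final objective is kept (ties go to the smallest seed). Replicas are the main defence against local optima of this non-convex objective. |
| `posWeight` | negatives/positives per pair | positive-class weight in scoring-model pretraining; without it the all-negative predictor dominates since positives are `O(L)` of `O(L^2)` entries. |

Other pinned numerical choices: EM for the prior uses k-means++ seeding,
at most 200 iterations and relative tolerance `1e-6`, with variances
clamped at `1e-6` (degenerate inputs cannot crash it); Viterbi ties are
broken deterministically, preferring Match over Delete over Insert at
each decoding decision; sequences longer than 10x the median are rejected
rather than silently truncated; the unknown residue `X` is emitted with a
fixed uniform-background probability at every state so it neither
attracts nor repels any column.

## Topology decisions

The profile topology is glocal: entry through `M_1`/`D_1`, exit through
`M_L`/`D_L`, no insert-to-delete or delete-to-insert transitions, one
shared insert/flank emission distribution. Domain repeats and fragment
handling are deliberately not modelled. The begin/end states make the
model a proper distribution over sequences (including the empty
sequence); the test suite verifies that the total probability of all
sequences up to length 12 on a two-letter toy model exceeds 0.999.

## What the synthetic data emulates — and what it does not

All tests and worked examples run on synthetic data from three
generators, each deterministic under a seed:

* `makeFamily()` draws match emissions from a symmetric Dirichlet with
  concentration `1/conservation` and uses a single `indelRate` for all
  indel and flank probabilities, then samples sequences with their true
  state paths, giving a family with a known gold-standard alignment and a
  designated 10-sequence reference subset. The two knobs mirror the
  identity and depth axes of curated benchmark collections.
* `makeAmbiguousFamily()` builds the embedding stress test: two
  subfamilies occupy disjoint halves of a `2k`-column alignment while
  sharing identical per-column amino-acid distributions, so the correct
  column assignment is unidentifiable from residues but fully recoverable
  from planted per-column embedding directions (strength 2 against unit
  noise, `r = 16`). A linear probe separates the subfamilies from the
  embeddings with accuracy above 0.95, and at signal strength 0 the probe
  drops to chance.
* `makePlantedPairs()` generates scoring-model training data in which
  aligned residues share a latent vector confined to a fixed
  12-dimensional subspace of the 32-dimensional embedding space — the
  low-rank premise of the scoring model. The latent dimensionality caps
  the achievable pair AUROC (positive scores are chi-square with
  `latentDim` degrees of freedom), which is why the planted subspace has
  a dozen dimensions rather than two or three.

The shipped embedder is synthetic: each residue's vector is a
deterministic pseudo-random function of its `w = 3` local sequence window
(`d = 32`), so it is context-sensitive and reproducible offline, but it
carries no evolutionary or structural information. Consequently, passing
tests demonstrate that the machinery — joint emissions, compression,
priors, training, decoding, scoring — works end to end and that genuinely
informative embeddings are exploited when present; they do not
demonstrate alignment-accuracy gains on real protein families, which
depend on real protein language models plugged in through
`registerEmbedder()`.

## Problem sizes

The shipped checks use problem sizes chosen to exercise each claim at
desk scale: path-enumeration oracles on models with up to 3 match states
and sequences up to length 4 (hundreds of random instances); parameter
recovery on 300 sequences from an 8-state peaked profile; the ambiguity
benchmark on 240 sequences of length 5 with 10 true columns, five
training seeds per arm; scoring pretraining on 40 sequence pairs of
length 10; and the depth-scaling timing on 1000 vs 2000 sequences at
fixed model length with a fixed number of epochs.

## Known limitations

* Training at inference time is non-convex; replicas mitigate but do not
  eliminate local optima. On the ambiguity benchmark individual seeds can
  fail to find the split even when the median run succeeds.
* Very shallow inputs (well under a hundred sequences) underdetermine the
  profile; the aligner warns and proceeds, but a conventional aligner is
  the better tool there.
* Runtime is linear in the number of sequences but cubic in sequence
  length, so very long proteins are comparatively expensive.
* The counting of prior parameters is documented as
  `C*r` means + `C*r` variances + `C` weights (1056 at `C = 32`,
  `r = 16`); published parameter counts for comparable priors sometimes
  use other conventions (e.g. 1040), and we pin ours explicitly rather
  than guess the difference.
* Insert residues are left-justified and not aligned to each other — the
  standard profile-alignment convention; column scores therefore only
  credit match columns.
* The exact tie conventions of established alignment-comparison tools are
  not fully documented; our SP/TC/column scores match residue coordinates
  (row id plus ungapped index), count columns with fewer than two
  residues as zero-pair columns for SP and the weighted column score but
  as ordinary columns for TC, and may differ from other implementations
  at those margins.

## A worked run

```{r example, eval = FALSE}
fam <- makeFamily(LM = 8, n = 300, conservation = 5, indelRate = 0.02,
                  seed = 11)
cfg <- trainingConfig(maxEpochs = 150, parallel = 2, seed = 3,
                      lengthOverride = 8)
best <- selectBest(fitProfiles(fam$seqs, config = cfg))
msa <- decodeMSA(best, fam$seqs)
evaluateAlignment(extractReferenceSubalignment(msa, fam$refIds),
                  extractReferenceSubalignment(fam$msa, fam$refIds))
```

The same pipeline, with embeddings, replaces the first step by
`precomputeCompressed()` (embed, compress, cache) and sets
`useEmbeddings = TRUE`; `scripts/acceptance.R` runs both variants end to
end and writes every quantity it measures to JSON.
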