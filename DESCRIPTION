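Package: dpHMM
Title: Deep Profile Hidden Markov Models for Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns large sets of unaligned protein sequences by fitting a
    profile hidden Markov model with gradient descent and decoding the
    multiple alignment from the fitted model. Match states can jointly emit
    amino acids and compressed per-residue embedding vectors under diagonal
    Gaussian emission models, so that context-sensitive sequence
    representations inform the alignment. Includes a low-rank bilinear
    scoring model that is pretrained on induced pairwise alignments and
    doubles as an embedding compressor, a mixture-of-Gaussians prior over
    match-state embedding means, a deterministic synthetic embedder for
    fully offline operation, reference-based alignment accuracy scores
    (sum-of-pairs, total column and weighted column scores), and simulators
    for protein families with known ground-truth alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
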