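Package: m6aCNN
Title: Branch Convolutional Neural Networks for N6-Methyladenosine Site
    Prediction in RNA Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts N6-methyladenosine (m6A) modification sites in RNA
    sequences with a three-branch convolutional neural network that fuses
    three sequence representations in feature space: a circular dinucleotide
    encoding (non-overlapping base pairs over the first-base-replicated
    sequence, one-hot over the 16 dinucleotides), per-base one-hot encoding,
    and nucleotide chemical property (NCP) encoding.  Provides the classic
    modelling interface (fit, predict, summary, plot), k-fold
    cross-validation with per-fold test and validation roles, ablation modes
    (input-space concatenation, encoding subsets), in silico mutagenesis
    maps for model interpretation, miCLIP-style positive/negative window
    construction from site tables, and a synthetic motif-implant sequence
    generator so the whole pipeline runs without external datasets.  The
    network (1-D convolutions, group normalization, dropout, Adam, early
    stopping) is implemented in vectorized base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
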