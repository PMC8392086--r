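---
title: "Predicting m6A sites with a branch CNN: model, encodings and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting m6A sites with a branch CNN: model, encodings and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6aCNN)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal modification of
mRNA and regulates splicing, export, stability and translation.
Experimental mapping (MeRIP-seq, miCLIP) is slow and costly, so sequence
classifiers that score whether a given adenosine is methylated from its
local sequence context are widely used.  The conventional setup is a
fixed-length, odd-length window centred on the candidate adenosine, with a
binary label; `m6aCNN` implements a three-branch convolutional classifier
for such windows together with the full protocol around it: encoding,
dataset construction, cross-validation, evaluation and interpretation.

## The three input representations

Each window is presented to the network in three complementary binary
representations.

**Circular dinucleotide encoding.**  The sequence is closed into a ring by
replicating the first base at the end; the ring is then read as
consecutive *non-overlapping* base pairs, left to right, so an
odd-length window of `L` nt yields `(L + 1) / 2` dinucleotides, the last
one joining the final base to the replicated first base.  Each pair is
one-hot encoded over the 16 ordered dinucleotides, giving a
`(L + 1) / 2 × 16` matrix.  This representation exposes adjacent-base
composition directly, rather than leaving it for the convolution to
discover.

```{r}
circular_pairs("AGU")
```

Two details here were genuinely open and were fixed as package policy:
pairs are non-overlapping (the worked encoding example in the original
description pairs positions (1,2), (3,4), ... — a sliding window would
give 2× more pairs), and the bit order of the 16 pair codes defaults to
lexicographic (`AA, AC, ..., UU`).  Any published bit assignment can be
substituted via `pair_code_table()`; predictions are invariant to a fixed
permutation of the 16 columns (the corresponding first-layer kernel
slices permute with them), which the test suite verifies numerically, so
this choice affects serialized encodings only.  Even-length input is
undefined for the ring construction; the encoders reject it by default
and offer an explicit lenient mode that drops the final unpaired base.

**One-hot encoding.**  `A, C, G, U` map to the rows of the 4×4 identity,
giving `L × 4`.

**Nucleotide chemical property (NCP) encoding.**  Each base is a 3-bit
vector over ring structure (purine = 1), hydrogen-bond strength
(weak = 1) and chemical group (amino = 1): A = (1,1,1), C = (0,0,1),
G = (1,0,0), U = (0,1,0), giving `L × 3`.

Input is canonicalized before encoding: uppercased, `T` mapped to `U`
(many benchmark files ship as DNA), and anything else — including IUPAC
ambiguity codes — rejected with the offending position named.  Ambiguity
codes are deliberately unsupported: none of the encodings has a defined
row for them, and silently substituting a base would contaminate labels.

## The network

Each representation feeds its own branch with an identical layer stack:

    conv(32 filters, size 5, stride 1) → ReLU → group norm (4 groups)
    → conv(16 filters, size 3, stride 1) → ReLU → flatten
    → dropout(0.5) → dense(24)

The three 24-unit branch features are concatenated into 72 hidden
features and a single sigmoid unit produces the m6A probability.  L2
penalties are attached to every convolution and dense kernel (`1e-3`) and
bias (`1e-4`).  Training uses Adam at learning rate 0.001, minibatches of
32, binary cross-entropy (probabilities clipped at `1e-7`), early
stopping on validation loss with best-weight restoration, and a cap of
1000 epochs.

The rationale for fusing in feature space rather than input space is that
each branch first transforms its raw, non-linearly structured encoding
into a representation in which the classes are closer to linearly
separable, and concatenation then happens between these learned features;
concatenating the raw encodings per position and pushing them through a
single branch (`arch = "input_concat"`) is retained as the ablation
baseline so the comparison is runnable on any dataset.

Points the original description leaves open, resolved as follows:

* **Padding** is not stated; the default is `"same"` (so flattened branch
  widths are `length × 16`), with `"valid"` supported and covered by the
  shape tests.  No pooling layers are used — none are described.
* **Group-norm placement** follows the stated layer order exactly
  (after the first ReLU), although pre-activation placement is more
  common elsewhere.  Scale/shift parameters are not L2-penalized.
* **The branch dense layer** uses a ReLU activation, making each branch
  a proper non-linear projection; only the output unit is sigmoid.
* **"Learning rate reduction factor 0.01"** is implemented as
  multiply-on-plateau: when the validation loss fails to improve for half
  the early-stopping patience, the learning rate is multiplied by the
  factor, with a floor of `1e-6`; it can be disabled.
* **"1000 training iterations"** is read as an epoch cap; early stopping
  makes it rarely binding.
* **Early-stopping patience** is not stated; the default is 50 epochs
  with best-weight restoration, configurable per call.
* **Classification threshold** for turning probabilities into calls
  is 0.5.
* **Weight initialization** is uniform Glorot with a user seed; the whole
  training loop (shuffling, dropout, initialization) runs off R's RNG, so
  a seed reproduces a fit bit for bit.
* **Single-branch input alignment**: the circular encoding has
  `(L + 1) / 2` rows against `L` for the others, so for the input-concat
  baseline each circular row is repeated for the two ring positions its
  pair covers (the final row once), aligning all encodings per position
  before feature-axis concatenation.

There is no deep-learning framework dependency: forward and backward
passes for the 1-D convolutions (im2col form), group normalization,
dropout and dense layers, together with Adam, are implemented in
vectorized base R against BLAS.  The gradients are validated against
central finite differences in the test suite, and the convolution input
gradient uses the identity that the adjoint of a stride-1 convolution is
a convolution with the position-flipped, channel-transposed kernel.

## Evaluation protocol

`cross_validate()` reproduces the k-fold protocol: records are split into
`k` mutually exclusive, stratified folds; per round one fold tests, the
*next* fold (cyclically) validates for early stopping, and the remaining
`k − 2` train.  Per-round metrics are averaged arithmetically, with
standard deviations, rather than pooling confusion counts.  Fold seeds
are derived as `seed + round`, so folds are independent but a run is
reproducible from one integer.  Stratification is on by default (a flag
disables it); with balanced data it changes little, but it guarantees
every test fold contains both classes.

Metrics are accuracy, sensitivity, specificity, MCC, F1 and AUC, computed
from the thresholded confusion table; AUC is the tie-aware rank statistic
(probability that a random positive outranks a random negative, ties
counting one half), which is equivalent to trapezoidal ROC integration
for continuous scores and remains well defined with ties.  Single-class
inputs return the defined metrics and flag the rest as `NaN` with a
warning rather than erroring, so degenerate folds surface visibly.

## miCLIP-style dataset construction

For single-base-resolution site tables, `merge_sites()` collapses
clustered sites (m6A agglomerates): maximal runs in which consecutive
sites lie within 50 nt are replaced by their median-position member
(even runs keep the lower of the two middle sites).  Transitive runs make
the result order-independent and idempotent.  `build_positive_windows()`
places each merged site at a uniformly random offset inside a 101-nt
window constrained to the transcript; `build_negative_windows()` scans
candidate windows at ±10, ±20, ... (100 steps per side) from each
positive's centre, keeps the nearest candidate per side that lies inside
the transcript and contains *no* site from the merged table, and picks
one of the two by a fair coin — a deliberate reading of "selected one
sample randomly" as an unweighted coin even when the two distances
differ.  Note that the positive's own site also excludes candidates, so
the nearest possible negative centre is always more than 50 nt away.
Coordinates are 1-based closed intervals throughout, matching the
R/Bioconductor convention.

## The synthetic benchmark generator

`simulate_dataset()` emulates the statistical shape of the centred
benchmark datasets so the whole pipeline is testable without downloads:
fixed odd length (default 41 nt), balanced classes, `A` forced at the
centre of *both* classes, positives carrying a motif implanted around the
centre.  The default motif is the canonical GGACU consensus (the most
common DRACH instance) as a deterministic base table; the `noise`
parameter replaces each implanted base by a background draw with the
given probability, and is the single knob controlling class
separability — at `noise = 0` every positive contains GGACU exactly, at
`noise = 1` positives are indistinguishable from background.  The
background composition defaults to uniform and is configurable.  With
`noise = 0.1`, enumerating the four informative flank positions gives a
Bayes-optimal accuracy ceiling of about 0.96 and AUC about 0.99, so a
well-trained classifier is expected in the mid-0.9s — comparable to the
published benchmark regime.

What the generator does *not* emulate: positional composition gradients,
transcript-level dependence between windows, multiple or degenerate
motif occurrences per window, and secondary structure.  Tests passing on
this generator therefore demonstrate that the implementation learns and
localizes a planted consensus under noise — not that any particular
accuracy transfers to real miCLIP data.

`simulate_site_table()` generates random transcripts with a configurable
fraction of tightly clustered sites to exercise the merging and
negative-window logic.

## Interpretation by in silico mutagenesis

`mutagenesis_map()` substitutes every base at every position of every
record, re-encodes each mutant from scratch (a single substitution moves
up to two circular pairs, and position 1 also moves the ring-closing
pair), and averages `|p(mutant) − p(reference)|` over records into an
`L × 4` map.  All four bases are substituted, including the resident one,
so the four-row map carries structural zeros on the resident base — at
the centre column the `A` row is zero for every centred dataset; an
option excludes self-substitutions from each cell's average instead.
Averaging is an unweighted mean over records, and the records averaged
can be restricted to positives or negatives (`subset=`), defaulting to
all.  On a model trained on the synthetic benchmark the map peaks inside
the implanted motif window, reproducing the centre-heavy effect expected
for centred m6A windows.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` size their runs so the whole
pipeline is exercised end to end at desk scale: the cross-validation and
ablation checks use 1000 positives + 1000 negatives at 41 nt with
`noise = 0.1`, 10-fold CV for the main run and 5-fold over three seeds
for the fusion ablation, training with patience 5 and an epoch cap of 25
(the planted-motif problem converges within a handful of epochs, so the
shorter schedule changes nothing but wall time relative to the
50/1000 defaults).  Mutagenesis maps average every tenth record.  Unit
tests use a reduced network (8/4 filters, 6 branch units) on shorter
windows.

## Known limitations

* Training is CPU-bound R; it is comfortable at benchmark scale
  (thousands of 41–101-nt windows) but not intended for
  transcriptome-scale training sets.
* The classifier consumes fixed-length windows; applying it
  transcriptome-wide requires windowing upstream.
* `NaN` metrics on single-class folds are propagated, not imputed; with
  stratified folds (the default) they do not occur.
* The synthetic generator's independence assumptions are listed above;
  conclusions about real data require the real benchmark datasets.
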