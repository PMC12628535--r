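---
title: "Multi-view contrastive learning for RNA methylation site prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view contrastive learning for RNA methylation site prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methclr)
```

## Scope and model

`methclr` classifies fixed-length RNA windows (default 41 nt, the
standard for curated modification-site benchmarks) as methylated or
unmethylated at their central position. The design assumption is a
sample-limited regime — hundreds rather than tens of thousands of
labeled windows — where the decisive modeling choice is not network
capacity but regularization: a contrastive objective over stochastically
augmented views forces representations that do not depend on any single
feature element, which is what makes the supervised head generalize from
few labels.

Two encodings of the same window act as complementary views:

1. **k-mer token view.** Overlapping k-mers (stride 1) bracketed by
   `[CLS]`/`[SEP]` give `L0 - k + 3` tokens over a vocabulary of
   `4^k + 5` (all DNA k-mers plus `[CLS]`, `[PAD]`, `[UNK]`, `[SEP]`,
   `[MASK]` at reserved indices 1–5). Uracil maps to thymine only at
   vocabulary lookup, so RNA and DNA inputs tokenize identically;
   the token strings shown to the user keep the original alphabet.
   Tokens are embedded by a trainable lookup table; a frozen per-token
   table exported from a pretrained DNA language model can be loaded
   with `pretrained_backend()` when such weights are available locally.
2. **CGR state view.** The chaos-game representation iterates
   `p_i = p_{i-1} + alpha (v_{x_i} - p_{i-1})` from the square centroid
   with `alpha = 0.5`; the scalar state `State_i = p_i^y - p_i^x`
   collapses each coordinate to one channel. Because the map is a
   contraction, position *j*'s influence on the coordinate at position
   *m* is bounded by `alpha^(m-j) * sqrt(2)` — the encoding is a
   geometrically weighted memory of the local sequence, which is what
   the second BiLSTM consumes.

Branch 1 (CNN → ReLU → batch norm → dropout → BiLSTM → 4-group group
norm → dropout → additive attention pooling) and branch 2 (BiLSTM over
the CGR states, final-state summary) each produce 128-d vectors whose
concatenation `h` feeds a 256→128→64→2 softmax classifier and — during
training only — a projection head to the 64-d space where the NT-Xent
loss is computed. The projection head is discarded at inference:
classification always consumes `h`, never `z`. Besides the usual
empirical argument for this split, projecting before the similarity
matrix reduces the pairwise-similarity cost from `O(B^2 D)` to
`O(B^2 P) + O(B D P)`, which pays off once the batch is large relative
to `P`.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `k` | 6 | k-mer size; 6 is the strongest variant of the 3–6 family and the package default. |
| `embed_dim` | 32 | lookup-table width; 768 restores parity with transformer-scale features at ~25x the embedding parameters. |
| `L0` | 41 nt | benchmark window length; configurable. |
| `conv_filters`, `kernel` | 64, 3 | the reference architecture leaves the CNN unspecified; 64 width-3 filters with same-padding is the conventional motif-detector setting. |
| `lstm_hidden` | 64/direction | fixed by the reference architecture, both branches. |
| `p_mask` | 0.15 | masking probability on token embeddings; grid-search optimum over {0.05,…,0.25}. |
| `eta` | 0.01 | Gaussian noise s.d. on CGR states (state units); optimum over {0.005,…,0.04}. |
| `tau` | 0.5 | NT-Xent temperature; unspecified by the reference, set to the original SimCLR small-batch value. |
| `proj_dim` (`P`) | 64 | unspecified; 64 matches the dimensionality used in the downstream representation analyses and satisfies `P << dim(h)`. |
| `lambda` | 0.5 start, floor 0.3 | multi-task weight; fixed for 10 epochs, then ±0.05 per trigger following the sign of the least-squares slope of validation accuracy over a 5-epoch window. |
| `base_lr`, batch, optimizer | 1e-3, 32, Adam | unspecified by the reference; standard desk-scale choices, configurable. |
| patience | 15 epochs | early stopping on validation accuracy, restoring the best checkpoint. |

Dropout is 0.3 after the convolutional block and after the BiLSTM block
of branch 1, and 0.1 in the dense layers of both heads. The stated
placement ("following the convolutional and BiLSTM layers") is ambiguous
about whether one or both sites are meant; we apply it at both.

## Training-loop decisions

Several points the reference leaves open were decided once and are
flagged here rather than buried in code:

* **Which pass feeds the supervised loss.** The classification loss is
  computed on the clean (unaugmented) forward pass, so the classifier
  never sees corrupted inputs; `cls_input = "augmented"` averages it
  over the two views instead.
* **Joint vs. two-stage.** The default is single-stage joint
  optimization of `L_cls + lambda L_cont`. Because the projection head
  is described as discarded "after pre-training", a two-stage mode
  (`schedule = "two_stage"`: contrastive-only pretraining, then joint)
  is available behind a flag.
* **Masking granularity.** "Feature elements" is read as element-level
  masking of the embedding matrix; whole-token-row masking is available
  via `granularity = "token"`.
* **Warm-up shape.** The 5-epoch warm-up is a linear ramp from
  `base_lr/5`; decay thereafter is per-epoch at rate 0.9. Only the
  5-epoch length and the 0.9 rate are prescribed; ramp shape and
  granularity are ours.
* **Embedding backend.** Whether the pretrained language model is
  fine-tuned inside the pipeline is unstated; the package freezes any
  loaded pretrained table (feature-extractor mode) and makes the lookup
  fallback trainable end-to-end, which keeps CPU training tractable and
  reproducible.

## Numerical choices and degenerate inputs

* Cross-entropy clamps predicted probabilities at `1e-12`, so a
  confident wrong prediction yields a large finite loss.
* The internal NT-Xent path clamps projection norms at `1e-8`; the
  projection output bias is initialized slightly off zero so no
  projection starts exactly at the origin (where cosine similarity is
  undefined). The exported `cosine_similarity()` /
  `ntxent_batch_loss()` keep the strict zero-vector error.
* Metrics with vanishing denominators (degenerate folds) are reported
  as 0 and listed in a `degenerate` attribute instead of aborting a
  cross-validation run.
* AUROC is computed by the rank identity (ties counting one half),
  which equals trapezoidal integration of the empirical ROC curve;
  AUPRC integrates the PR curve trapezoidally with recall 0 anchored at
  the first threshold's precision.
* Gap characters (`-`, terminal padding) carry no sequence identity:
  the CGR update is skipped (`p_i = p_{i-1}`, state repeated), any
  k-mer containing a gap maps to `[UNK]`, and perturbation importance
  does not substitute into gap positions. The reference never specifies
  gap behavior; these conventions avoid fabricating geometry or
  vocabulary from padding.
* Weights use uniform Glorot initialization; LSTM forget-gate biases
  start at 1. All initialization and every stochastic training choice
  (shuffling, dropout, masks, noise) derive from the run's seed, so a
  fixed master seed reproduces the entire training history bit-for-bit.
* Non-finite losses abort training immediately with a diagnostic rather
  than silently optimizing on NaNs.
* Batch-norm running statistics (momentum 0.9) are updated on every
  training-mode forward pass, including the two augmented passes; eval
  mode uses the running statistics, which is why all inference-time
  outputs are deterministic.

The t-statistic for representation analysis uses the Welch
(unequal-variance) form; the variant is unstated in the reference and
Welch is the safer default when class-conditional variances differ.

## The synthetic benchmark: what it does and does not show

`generate_dataset()` emulates the *structure* of curated
modification-site benchmarks: balanced 1:1 classes, fixed 41-nt windows,
and a positional class signal — an IUPAC motif (default `GGACU`, the
m6A-like consensus, centered) carried by positives with probability
`insertion_prob` and rejection-excluded from negatives at the planted
offset only. Defaults (400+400 windows, test fraction 0.25) give the
600-train / 200-test split used by the package's end-to-end checks,
chosen as a desk-scale analogue of the smallest real benchmark
(605 training / 86 test positives for m7G).

What it deliberately does not emulate: the k-mer spectrum, positional
base composition and motif degeneracy of real methylation contexts, or
inter-sequence redundancy. Passing the end-to-end checks therefore
demonstrates that the pipeline can extract a planted, linearly separable
signal and that it fabricates none when `insertion_prob = 0` — it does
not certify performance on real epitranscriptomic data, which requires
the external benchmark datasets.

Problem sizes throughout the test suite were chosen as the smallest that
make each property observable: the full-default end-to-end runs use
600/200 windows; the branch-ablation comparison uses 21-nt windows with
a 75%-penetrant motif (180/60 windows, medians over 3 seeds) so that
neither view saturates and the dual-branch advantage is measurable; the
training-contract checks use 15-nt windows at reduced widths.

## Known limitations

* Training is pure-R CPU code: practical up to a few thousand windows,
  not for the 40k-positive benchmarks of common modifications.
* The pretrained backend consumes a static per-token embedding table;
  contextual (per-occurrence) transformer features are out of scope
  offline.
* Negative sampling in the contrastive batch treats all other windows
  as negatives; no hard-negative mining or class-aware pairing.
* `branch2_summary = "mean"` and the two-stage schedule are provided but
  not part of the tested default path.
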