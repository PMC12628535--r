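# methclr

Multi-view contrastive learning for RNA methylation site prediction in R.

## The problem

RNA methylation marks (m⁶A, m⁷G, m⁵C, the 2′-O-methylations Am/Cm/Gm/Um,
and related modifications) regulate RNA stability, translation and
localization. Wet-lab mapping of modification sites is expensive, so
sequence-based classifiers are trained on curated benchmarks: balanced
sets of 41-nt windows centered on a candidate site, labeled modified /
unmodified. For rare marks these benchmarks are small — a few hundred
positives — and conventional deep networks overfit badly at that scale.

`methclr` targets exactly this sample-limited regime. It is written for
computational epitranscriptomics researchers who want a trainable,
inspectable site classifier that runs on a plain CPU, plus the machinery
to generate synthetic benchmarks, evaluate rigorously and interrogate
what the model learned.

## The model

Each 41-nt window is encoded in two complementary views:

* **k-mer token view.** The window is decomposed into `L0 − k + 1`
  overlapping k-mers (default `k = 6`), bracketed by `[CLS]`/`[SEP]`, and
  embedded via a trainable lookup table over the `4^k + 5`-token
  vocabulary (a frozen pretrained per-token embedding table can be
  substituted). A 1-D convolution extracts local motif features, a
  bidirectional LSTM (64 units per direction) models long-range context,
  and additive attention pools the per-position features into a context
  vector *c*:
  `e_t = v⊤ tanh(W_a h_t + b_a)`, `a = softmax(e)`, `c = Σ_t a_t h_t`.
* **Chaos-game-representation (CGR) view.** The window is mapped into the
  unit square by the iterated function system
  `p_i = p_{i−1} + α (v_{x_i} − p_{i−1})` with `α = 0.5`,
  `p_0 = (0.5, 0.5)` and vertices A=(0,0), C=(0,1), G=(1,1), T/U=(1,0);
  each coordinate is collapsed to the scalar state
  `State_i = p_i^y − p_i^x`. A second BiLSTM summarizes this geometric
  trace.

The fused representation `h = [c ; summary]` (256-d) feeds two heads:

* a **classifier** (dense 256 → 128 → 64 → 2, softmax) trained with
  cross-entropy `L_cls`;
* a **projection head** (MLP to `P = 64` dimensions, training only) on
  which the SimCLR-style NT-Xent contrastive loss is computed. Every
  sample yields two stochastically augmented views — random feature
  masking (`p_mask = 0.15`) on the token embeddings, additive Gaussian
  noise (`η = 0.01`) on the CGR states — and for a mini-batch of N
  samples the 2N projections are pulled together pairwise and pushed
  away from the 2(N−1) other views:

  `ℓ_{q,k} = −log [ exp(sim(z_q, z_k)/τ) / Σ_{j≠q} exp(sim(z_q, z_j)/τ) ]`,
  `L_cont = (1/2N) Σ_k [ℓ_{2k−1,2k} + ℓ_{2k,2k−1}]`, `τ = 0.5`.

Training optimizes `L_total = L_cls + λ·L_cont` with Adam under a 5-epoch
warm-up / 0.9-decay learning-rate schedule. The weight λ starts at 0.5,
stays fixed for 10 epochs, then adapts within [0.3, 0.5] following the
5-epoch trend of validation accuracy. Early stopping (patience 15)
restores the best-validation checkpoint. The contrastive term acts as a
regularizer that is the point of the architecture: it forces
augmentation-invariant representations when labels alone are too few.

The entire network — convolution, BiLSTMs, attention, batch/group
normalization, both heads, and backpropagation through all of it — is
implemented in vectorized base-R matrix code and is exercised by
finite-difference gradient checks in the test suite.

## Worked example

```r
library(methclr)

ds <- generate_dataset(synthetic_config(n_pos = 200, n_neg = 200, seed = 42),
                       test_frac = 0.25)
model <- mv_model(model_config(seed = 42))
fit <- train_model(model, ds$train,
                   config = train_config(epochs = 20, seed = 42))

ev <- evaluate_model(fit$model, ds$test)
print(ev$metrics)
#> <metric_report> Acc 0.7900  Sn 0.9600  Sp 0.6200  Pre 0.7164  F1 0.8205  MCC 0.6167
cat(sprintf("AUROC %.4f  AUPRC %.4f\n", ev$auroc, ev$auprc))
#> AUROC 0.8544  AUPRC 0.7996
```

The synthetic benchmark plants a fully penetrant `GGACU` motif at the
window center of positives, so these numbers measure how well the full
pipeline recovers a known signal from 300 training windows; at the
package's default scale (600 training windows) the same pipeline exceeds
0.95 AUROC. The classic confusion-matrix worked example — the unique
counts consistent with a balanced 86+/86− test split at sensitivity
83.72% and specificity 77.91% — is built in:

```r
m <- classification_metrics(worked_confusion_fixture())
print(m)
#> <metric_report> Acc 0.8081  Sn 0.8372  Sp 0.7791  Pre 0.7912  F1 0.8136  MCC 0.6173
```

Interpretability helpers (`gradient_importance()`,
`perturbation_importance()`, `feature_t_stats()`) profile which window
positions and representation dimensions drive the prediction;
`cross_modification_matrix()` measures transfer between modification
types, and `repeated_runs()` quantifies run-to-run stability.

## Command line

```sh
inst/scripts/methclr fixtures --out data --n-pos 400 --n-neg 400 --seed 1
inst/scripts/methclr train --config run.yaml
inst/scripts/methclr evaluate --checkpoint out/model.rds --test data/test.tsv
inst/scripts/methclr predict --checkpoint out/model.rds --input sites.fasta
inst/scripts/methclr gridsearch --config run.yaml
```

Every command writes its resolved configuration next to its outputs, so
runs replay from the config file alone.

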