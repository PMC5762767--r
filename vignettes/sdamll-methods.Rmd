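---
title: "Methods: stacked denoising autoencoders and pairwise-ranking multi-label learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked denoising autoencoders and pairwise-ranking multi-label learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdamll)
```

## Scope and data model

`sdamll` predicts multi-label pathway membership for genes described by
sparse term-frequency vectors. The container is a `multilabel_dataset`:
an `m x d` feature matrix with every value in `[0, 1]` and, per instance,
a non-empty subset `Y_i` of a label universe of size `N`. Internally
labels are 1-based indices into `label_names`; on disk (TSV/MTX + label
TSV) they are always names. `validate_dataset()` reports violations
instead of throwing, so pipelines can surface all defects at once.

An instance whose label set is the *entire* universe is valid data but is
degenerate for the pairwise error below (its complement is empty) and for
ranking loss. Training skips such instances with a message; the metrics
reject them outright, and the cross-validation harness filters them from
validation scoring before calling the metrics. The synthetic generator
never produces them.

## The denoising autoencoder

One layer is an encoder `y = s(Wx + b)` and decoder `z = s(W'y + b')`
with the logistic sigmoid and *tied weights*: we take `W' = t(W)`
(`b'` stays free), the standard tied-weight convention, halving the
parameters. Corruption is masking noise: exactly `floor(v * d)` input
coordinates, drawn uniformly without replacement, are set to zero; the
reconstruction target is the clean input. The floor is our choice of
rounding rule — the corrupted count is specified only as the product
`v*d`.

Two reconstruction losses are supported: squared error
`sum((x - z)^2)` and Bernoulli cross-entropy
`-sum(x*log(z) + (1-x)*log(1-z))`, the default, which is the natural
choice for inputs scaled into the unit interval. Under cross-entropy a
reconstruction of exactly 0 or 1 (possible only through saturation) is
clamped to `[1e-12, 1 - 1e-12]`, with a message.

Training is deliberately plain: per-instance SGD in a freshly shuffled
order each epoch, fixed learning rate, no momentum, weight decay or
minibatching. The per-epoch trace records the mean loss on *clean*
inputs, so traces are comparable across corruption levels. Weights are
initialized uniformly on `±4·sqrt(6/(d + d'))` (the classical sigmoid
scaling); biases start at zero. Stacking is greedy: each layer trains on
the codes of the layers below, with corruption applied to its *own*
input; `sda_transform()` applies no corruption.

The single-step gradients live in R (`dae_gradients`, checked against
central finite differences at random parameter points in the test suite)
and the epoch loop is compiled (RcppArmadillo) for speed; a suite test
asserts the compiled loop reproduces the R reference loop
entry-for-entry, so the compiled path inherits the finite-difference
guarantee.

## BP-MLL

The classifier is a single-hidden-layer feed-forward network
`c = s(t(W) s(t(V) x + gamma) + theta)` trained on the pairwise
exponential error

$$E_i = \frac{1}{|Y_i|\,|\bar Y_i|} \sum_{(k,l) \in Y_i \times \bar Y_i}
\exp(-(c_k - c_l)),$$

whose value is 1 when all outputs are equal and decays as relevant
outputs separate upward from irrelevant ones. The published update rules
for this error leave the output- and hidden-layer deltas `d_j`, `e_s`
unspecified; we derive them by the chain rule through the sigmoid:

- relevant `j`: `d_j = z * exp(-c_j) * sum_{l irrelevant} exp(c_l) * c_j(1-c_j)`
- irrelevant `j`: `d_j = -z * exp(c_j) * sum_{k relevant} exp(-c_k) * c_j(1-c_j)`
- `e_s = (sum_j d_j w_sj) * b_s (1-b_s)`,

with `z = 1/(|Y||Ybar|)`. The factorized sums make an update O(N + M·N)
rather than O(|Y|·|Ybar|·N). Correctness is enforced by the
finite-difference oracle in the tests, not by trusting the algebra.
Updates are exactly linear in the learning rate `alpha`, and the additive
form `param += alpha * delta` descends `E_i`.

Training is online (one instance at a time, shuffled each epoch). After
each epoch the global error `E` on the clean training set is computed;
training stops when `E` has not decreased by more than `tol = 1e-9` for
`patience` (default 3) consecutive epochs, or at `max_epochs`. The
tolerance-plus-patience reading of "stops when the error doesn't
decrease" avoids hair-trigger stops on float noise. We use the sigmoid
throughout because it is the only activation the model family names; the
wider BP-MLL literature often uses tanh with thresholded outputs — a
known deviation, deliberate, so the encoder and classifier share one
nonlinearity.

`SdaMLL = pretrain -> freeze -> BP-MLL on codes`. Whether the original
formulation fine-tuned the stack supervisedly is unstated; we freeze the
encoder, which keeps the two stages' responsibilities clean (and lets the
empty-stack path double as the raw-feature BP-MLL baseline with
bit-identical code). The default architecture is a single code layer of
`min(200, ceiling(d/2))` units — for high-dimensional term spaces this is
the `d -> 200` compression the method is built around.

## Ranking metrics

`rank_f(x, l)` is 1 plus the number of labels scored strictly above `l`,
plus the number of *tied* labels with smaller index. This deterministic
total order matters: a freshly initialized network outputs near-constant
scores, and without a fixed tie-break the metrics would be
run-to-run noise. The convention is pessimistic in exactly the way
ranking loss demands, since that metric counts ties (`f(y1) <= f(y2)`) as
violations. Coverage is the mean worst rank of a true label minus 1
(bounded by `N - 1`); average precision is the mean, over true labels, of
the fraction of labels at-or-above them that are true. All three are
checked against a naive pair-enumeration oracle to `1e-12` in the test
suite, over a thousand random instances.

## Baselines

Both baselines are binary-relevance adaptations producing the
real-valued scores the ranking metrics need. KNN scores label `l` by the
fraction of the `k = 10` Euclidean nearest training instances carrying
`l`, with distance ties broken by training index. The decision-tree
baseline grows one Gini tree per label via `rpart` (depth-30 cap, i.e.
effectively unlimited, minimum leaf 2) and scores by the positive
fraction in the reached leaf. `k`, the depth policy and the distance
metric are unstated in the method family we follow; these defaults are
the standard ones. Neither baseline uses randomness.

## Synthetic data: what it emulates and what it does not

The generator emulates the statistical skeleton of a literature-mined
gene-by-term matrix: each of `N` pathway labels owns a disjoint (by
default) set of `signature_terms_per_label` terms; a gene samples its
label-set size uniformly from `{1, 2, 3}`, then its labels; counts are
Poisson with mean `signal_strength = 5` on signature terms of owned
labels and `background_rate = 0.05` elsewhere; columns are max-scaled to
`[0, 1]`. With the study-scale defaults (500 genes, 8 pathways, 2000
terms, 25 signature terms each) roughly 95% of cells are exact zeros —
the sparse regime the autoencoder is motivated by. The 25-term signature
size is our choice: large enough that signatures survive 30% masking
corruption, small enough that signature terms are ~10% of the vocabulary.

It does **not** emulate real text: no Zipfian term distribution, no
correlated synonym structure, no label imbalance, no noise in the label
assignments themselves. Passing the recovery tests therefore shows the
pipeline can extract a planted low-dimensional signal through the
compress-then-rank path — not that it reaches any particular accuracy on
mined corpora, whose difficulty (overlapping vocabularies, noisy labels)
the generator deliberately omits. Performance *ordering* between SdaMLL
and raw-feature BP-MLL on real data is a real-data claim and is not
asserted anywhere in the suite; both are only required to beat the
label-permutation null.

## Numerical and design choices

- **Seeding.** Every stage derives named sub-seeds from one root seed
  (`stream_seed`), so corruption, initialization, shuffling, folds and
  simulation are independently reproducible; all CLI outputs are
  byte-identical across reruns (numbers are printed with 9 significant
  digits, model arrays with 17).
- **Hyperparameter defaults** (the method family states none): DAE —
  10 epochs, learning rate 0.05, corruption `v = 0.3`, cross-entropy;
  BP-MLL — 32 hidden units, `alpha = 0.05` (the admissible range is the
  open unit interval), 50 max epochs, patience 3, init uniform `±0.05`.
  Chosen once as conventional values for sigmoid nets of this size.
- **Cross-validation** uses plain random folds (sizes within 1), not
  label-stratified — matching the protocol we reproduce; a method failure
  on a fold is recorded and the run continues. Fold aggregation reports
  the mean over folds (a pooled aggregate would weight folds by size;
  with near-equal folds the difference is negligible, and the per-fold
  table is retained so either can be recomputed).
- **Permutation nulls** recompute a statistic under random reassignment
  of the label sets to instances, preserving the label-set marginal
  exactly. For CV statistics the null permutes labels under *fixed*
  held-out scores — the scores' dependence on the training labels is part
  of the observed statistic, not of the chance reference.
- **Problem sizes in the checked experiments**: signal recovery runs
  10-fold CV at 500 x 2000 with a 200-permutation null; the no-signal
  control uses a single 80/20 split at the same scale. These sizes give
  the nulls ~2-3 digit quantile resolution while keeping the full suite
  in the minutes range on one core.

## Known limitations

- No supervised fine-tuning of the encoder; no minibatching, momentum or
  adaptive optimizers; single hidden layer in the classifier.
- Cross-entropy reconstruction treats features as independent Bernoulli
  parameters, which is a modelling convenience for scaled counts, not a
  likelihood.
- The threshold rule of `predict_labels()` can return empty sets (it
  reports when it does); the ranking metrics themselves never need it.
- MatrixMarket files carry no dimnames, so ids/terms ride in `.rows` /
  `.cols` sidecar files; moving an `.mtx` without its sidecars loses the
  names (reading still works, with generated ids).
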