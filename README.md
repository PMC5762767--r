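# sdamll

Multi-label annotation of genes to pathways from sparse term-frequency
features, by stacked denoising autoencoder pretraining followed by a
pairwise-ranking neural classifier (SdaMLL).

## The problem

Literature mining turns a collection of gene-related full-text articles
into a gene-by-term matrix of term frequencies scaled to `[0, 1]`. Each
gene belongs to one or more pathways, so assigning pathway membership is a
multi-label classification problem over an extremely sparse,
high-dimensional feature space — most entries of any gene's term vector
are zero. `sdamll` is for computational biologists who want to train,
evaluate and compare multi-label rankers on this kind of data, and for
anyone who needs a tested reference implementation of the two building
blocks and the three ranking metrics involved.

## The model

**Denoising autoencoder (DAE).** An encoder
`y = s(Wx + b)` and tied-weight decoder `z = s(Wᵀy + b′)` (logistic
sigmoid `s`) are trained by per-instance SGD to reconstruct a clean input
`x ∈ [0,1]^d` from a corrupted copy `x̃` in which exactly `⌊v·d⌋`
coordinates are zeroed at random. The reconstruction error is either the
squared error `Σ(x_j − z_j)²` or the Bernoulli cross-entropy
`−Σ [x_j ln z_j + (1−x_j) ln(1−z_j)]` (the default). Stacking is greedy
and layer-wise: layer *k*+1 trains on the codes of the first *k* layers.

**BP-MLL.** A single-hidden-layer network `c = s(Wᵀ s(Vᵀx + γ) + θ)`
trained online on the pairwise exponential ranking error

    E_i = (1 / |Y_i||Ȳ_i|) · Σ_{(k,l) ∈ Y_i×Ȳ_i} exp(−(c_k − c_l)),

which penalizes every irrelevant label `l` scored near or above a
relevant label `k`. Training stops when the global error `E = Σ E_i` has
not decreased for `patience` epochs or at the epoch threshold.

**SdaMLL** is the composition: pretrain the stack on the features alone
(unsupervised), freeze it, and train BP-MLL on the codes. With an empty
stack the same code path yields the plain BP-MLL baseline on raw features.

**Evaluation** uses the three label-ranking metrics — coverage (average
worst rank of a true label, minus 1), ranking loss (fraction of
mis-ordered (relevant, irrelevant) pairs, ties counted as violations) and
average precision — plus KNN and decision-tree baselines, a seeded
10-fold cross-validation harness, and label-permutation nulls for
"better than chance" statements.

## Worked example

```r
library(sdamll)

spec <- synthetic_spec(n_instances = 200, n_labels = 8, n_terms = 500,
                       signature_terms_per_label = 25,
                       signal_strength = 5, background_rate = 0.05, seed = 7)
ds <- generate_dataset(spec)
ds
#> multilabel_dataset: 200 instances x 500 features, 8 labels
#>   sparsity (exact zeros): 85.8%
#>   mean labels/instance: 1.95

model <- sdamll_fit(ds, seed = 7)
model
#> sdamll_model
#>   encoder: 500 -> 200
#>   classifier: 200 -> 32 -> 8 (50 epochs)

res <- run_comparison(ds, methods = c("sdamll", "knn"), k = 5, seed = 7)
res
#> 5-fold cross-validation (seed 7)
#>  method average_precision ranking_loss coverage
#>  sdamll                 1        0.000     0.95
#>     knn                 1        0.002     0.95
```

The generator plants a disjoint 25-term "signature" per pathway, so each
gene's owned pathways leave a strong term-frequency trace; 85.8% of the
matrix is exactly zero. `sdamll_fit` compresses the 500-term space to a
200-dimensional code and trains the ranking classifier on the codes. In
the cross-validated comparison both methods rank essentially perfectly on
this easy, well-separated fixture (average precision 1 means every true
pathway outranks every false one; coverage 0.95 means the worst-ranked
true pathway of a gene sits, on average, just below rank 2 — consistent
with ~2 labels per gene).

A command-line interface over the same functions ships at
`inst/cli/sdamll.R` with subcommands `simulate`, `train`, `predict`,
`evaluate`, `baseline` and `cv`; every run writes a `manifest.json`
(config, seeds, input digests) so outputs are byte-reproducible from the
manifest alone. Example configs are in `inst/extdata/`.

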