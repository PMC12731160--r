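# mogola

Supervised integration of aligned multi-omics data — mRNA expression,
DNA methylation, miRNA expression measured on the same patients — for
sample classification and biomarker discovery.

For each omics layer `m`, `mogola` builds a binary KNN
patient-similarity graph from cosine similarity and encodes it with a
hybrid graph neural network,

    Z1 = ReLU(D^-1/2 (S+I) D^-1/2 X W1)      # GCN
    Z2 = GAT(S, Z1)                          # attention re-weighting
    Z  = GCN(S, Z2)

then refines the embedding with a feature gate `σ(l(Z)) ⊙ Z` and a
per-sample confidence weight `σ(t(Z)) ⊙ Z`, where the confidence head
`t` is trained to regress the true-class probability (TCP) of a
per-omics classifier. The refined layers are concatenated and fused by
**Omics-Linked Attention (OLA)**: external-memory attention against
learnable per-head key/value memories with softmax-then-L1 double
normalization, so the attention map is `N × S` (samples × memory
slots) — linear in sample count — rather than `N × N`. Training is
two-stage: per-omics encoder pretraining under a class-weighted
cross-entropy, then frozen-encoder joint optimization of

    L = L_GS + λ1 (L_ce + L_mse) + λ2 L_OLA.

Prediction is transductive (test samples join the graph as unlabeled
nodes), evaluation uses repeated stratified 70/30 splits, and
biomarkers are ranked by masking importance: the drop in test macro-F1
when one feature is zeroed in the test samples.

All graph layers, the fusion mechanism and the two-stage Adam
optimization are implemented as dense-matrix forward/backward passes
in base R; the test suite checks every computational step against
independent loop-based oracles.

## Worked example

Since real multi-omics cohorts cannot ship in a package, the built-in
generator plants class-discriminative features and shared cross-omics
factors in Gaussian data (see the vignette for what this does and does
not emulate):

```r
library(mogola)

sim <- simulate_multiomics(sim_config(seed = 11))   # N=300, Q=3, 3 omics
cfg <- mogola_config(k = 5, hidden_dims = c(64, 64, 32),
                     epochs_pretrain = 200, epochs_main = 300, seed = 1)

report <- evaluate_mogola(sim$dataset, cfg)   # 5 stratified 70/30 splits
report[report$repeat_id %in% c("mean", "sd"), ]
#>   repeat_id        acc f1_weighted   f1_macro
#> 6      mean 0.92444444  0.92518626 0.91384884
#> 7        sd 0.05632796  0.05509011 0.05728894
```

Mean accuracy 0.924 means the model recovers the three planted classes
from the 90 held-out samples of each split almost everywhere; macro-F1
0.914 shows the minority class (20% of samples) is not being
sacrificed. Biomarker ranking on the first split:

```r
sp <- make_splits(sim$dataset$labels, 0.3, 1, seed = 1)$repeats[[1]]
model <- fit_mogola(sim$dataset, sp$train_idx, cfg)
imp <- feature_importance(model, sim$dataset, sp$test_idx)
head(imp, 3)
#>   omics  feature_id importance
#> 1 mirna mirna_f0053 0.02089366
#> 2 mirna mirna_f0069 0.02089366
#> 3 mirna mirna_f0009 0.01133995
```

`importance` is the macro-F1 lost when that feature is masked;
positive rows are the identified biomarkers. All three leading
features here are planted informative miRNA features of the
generator's ground truth. Single-split importance is quantized (a
masked feature either flips a borderline test sample or it does not),
so for stable rankings average the tables over the protocol's five
splits, as `scripts/acceptance.R` does.

A command-line wrapper over the same functions ships in
`inst/cli/mogola` (subcommands `simulate`, `train`, `evaluate`,
`biomarkers`, `gridsearch`, `ablate`; every run writes a JSON manifest
with config, seed and input hashes).

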