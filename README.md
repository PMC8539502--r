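# dgin

Graph neural networks for molecular property regression in R: predicting
lipophilicity (logP; logD at pH 7.4) and aqueous solubility (logS) directly
from SMILES.

The core is the composite **directed-edge graph isomorphism network
(D-GIN)** and its two sub-architectures. The **D-MPNN** phase keeps hidden
states on *directed* edges and forbids immediate backtracking:

    h⁰_uv = τ(W_init · cat(x_u, x_e_uv))
    m^{t+1}_uv = Σ_{k ∈ N(u)\v} h^t_ku          (t = 1..T)
    h^{t+1}_uv = τ(h⁰_uv + W_m · m^{t+1}_uv)

followed by incoming-edge aggregation into node states. The **GIN** phase
then refines node states with a learnable ε:

    h^{l+1}_u = MLP_l((1+ε_l)·h^l_u + Σ_{w∈N(u)} h^l_w)   (l = 1..T2)

and a sum-pooled graph embedding h_G = Σ_u h_u feeds a feed-forward readout
with one output per trained property. D-GIN chains both phases; D-MPNN stops
after the edge phase; GIN starts from raw atom features. Training uses Adam
on a masked multi-task squared-error loss (exact analytic gradients,
verified against finite differences), with checkpoint selection by combined
(summed per-property) RMSE on the evaluation split.

Around the models the package implements the complete study protocol:
six declarative atom/bond featurization schemas (ids 3–8), dataset
preprocessing (salt stripping, neutralization, logS range filter), seeded
81:9:10 splits, per-property minimum offsets, seven single-/multi-task
training strategies, best-of-two-runs selection, 100-replicate bootstrap
95% CIs, classical baselines (RF / SVM / KNN on ECFP-1024/1536/2048 or
MACCS fingerprints ± standardized descriptors), consensus averaging, the
experiment grid (24 settings for logD and logS, 12 for logP), mask-one-block
feature ablation, and a seeded synthetic molecule generator with additive
ground-truth properties so everything is testable offline.

## Worked example

Train a D-GIN on 500 synthetic molecules whose logP is an exact additive
function of composition plus Gaussian noise (σ = 0.1), and evaluate on the
held-out test split:

```r
library(dgin)

df     <- synthetic_dataset(500, seed = 11)          # smiles + logd/logs/logp
st     <- feat_strategy(3)                           # full node/edge schema
graphs <- lapply(attr(df, "molecules"), build_graph, strategy = st)
sp     <- split_dataset(nrow(df), seed = 11)         # 405 / 45 / 50
off    <- offset_fit(df[, "logp", drop = FALSE])
y      <- offset_apply(off, df[, "logp", drop = FALSE])

params <- gnn_params("dgin", d = st$d, b = st$b, hidden = 16,
                     T = 3, T2 = 2, n_out = 1, seed = 1)
fit    <- gnn_train(params, graphs, y, sp, epochs = 200,
                    batch_size = 4, lr = 0.01, seed = 1)
fit
#> <gnn_fit> DGIN, 200 epochs; best eval combined RMSE 0.1410 at epoch 128

ev <- gnn_evaluate(fit$params, batch_graphs(graphs[sp$test]),
                   y[sp$test, , drop = FALSE])
round(ev$combined, 3)
#> [1] 0.196
```

The test RMSE sits within twice the σ = 0.1 noise floor of the generator —
the network has essentially recovered the additive structure (a least-squares
oracle on the exact composition counts reaches ≈ 0.10 on the same split). A bootstrap CI for
that figure:

```r
yhat <- gnn_predict(fit$params, batch_graphs(graphs[sp$test]))
bootstrap_ci(yhat[, 1], y[sp$test, 1], seed = 1)
#>     lower     upper
#> 0.1487984 0.2053922
```

Classical baseline and consensus on the same data:

```r
Xtr <- featurize_baseline(df$smiles[sp$train],
                          list(fingerprint = "ECFP-1024", with_descriptors = FALSE))
Xte <- featurize_baseline(df$smiles[sp$test],
                          list(fingerprint = "ECFP-1024", with_descriptors = FALSE))
rf  <- fit_baseline("RF", Xtr, y[sp$train, 1], seed = 1)
cons <- consensus(predict(rf, Xte), yhat[, 1])
rmse(cons, y[sp$test, 1])
#> [1] 0.6501253
```

(The fingerprint-based forest is a weak model for this additive synthetic
property, so here the consensus sits between the two components — above the
GNN alone, and, as always, no worse than the mean of the component RMSEs.)

A thin command-line front end over the same functions lives at
`inst/cli/dgin.R` (subcommands `generate`, `featurize`, `train`, `predict`,
`grid`, `ablate`, `consensus`).

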