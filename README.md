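# cpifuse

`cpifuse` is an R toolkit for compound–protein interaction (CPI) affinity
regression with **local + global feature fusion**, aimed at virtual
screening workflows: train on a large affinity benchmark (KIBA-type
scores), fine-tune on a small assay-specific pEC50 set, rank a compound
library by predicted affinity, and filter candidates by docking score,
QikProp #stars and Lipinski's rule of five.

## The model

For a compound c (SMILES) and protein p (amino-acid sequence) the
predictor fuses four heads:

| head | input | architecture | out |
|---|---|---|---|
| compound local | label-encoded SMILES, fixed length 100 | embedding → 3× conv1d (32/64/96, kernels 4/6/8) → max-over-time | 96 |
| compound global | ECFP4 (1,024 bits) ⊕ molecular descriptors (z-scored) | dense + ReLU | 512 |
| protein local | label-encoded sequence, fixed length 1,000 | embedding → 3× conv1d (32/64/96, kernels 4/8/12) → max-over-time | 96 |
| protein global | AAC/DPC/CTD descriptors (567, z-scored) | dense + ReLU | 512 |

The concatenated **1,216**-dimensional joint representation passes through
a dense stack (1024 → 512 → 1, dropout 0.1) to the affinity ŷ. Training
minimizes MSE with Adam; evaluation reports MSE, concordance index
(CI = Σ_{yᵢ>yⱼ} h(ŷᵢ−ŷⱼ)/Z, ties scoring ½), R² and Pearson r, under a
1/6 held-out test + 5-fold cross-validation protocol. The network,
including backpropagation, is implemented in-package on BLAS matrix
operations — no deep-learning framework is required.

A synthetic benchmark generator plants a signal that needs *both* routes —
a substructure×sequence-motif interaction term (invisible to global
descriptors) plus an MW×hydrophobicity term (invisible to local
convolution windows) — so end-to-end behaviour is testable offline.
See `vignettes/cpifuse-methods.Rmd` for the full methods account.

## Worked example

```r
library(cpifuse)

# a 2,000-pair synthetic CPI dataset with the planted local+global signal
ds <- generate_cpi_dataset(200, 20, 0.5, signal_spec(), seed = 2024)
ds
#> <cpi_dataset> 2000 interactions between 200 compounds and 20 proteins (scale: pEC50)

split <- make_split(ds, seed = 2024)                 # 333 test + 5 folds of ~334
model <- train_cpi(ds,
                   train_idx = sort(unlist(split$folds[1:4])),
                   val_idx   = split$folds[[5]],
                   train_config(max_epochs = 15, patience = 4, seed = 2024))

feats <- prepare_features(model$featurizer, ds)
test  <- cpifuse:::subset_features(feats, split$test_indices)
evaluate_predictions(test$y, predict(model, test))
#> MSE 0.1342 | CI 0.9013 | R2 0.9305 | PCC 0.9701
```

The held-out MSE (0.13) sits close to the planted noise floor
(σ² = 0.0625), R² ≈ 0.93 says the model recovers most of the planted
local+global variance, and CI ≈ 0.90 that it ranks unseen pairs
consistently — the property a virtual screen relies on.

Screening a ranked library then reduces to table algebra:

```r
top  <- select_top_fraction(ranked_table, 0.10)       # top decile by pEC50
hits <- apply_candidate_filters(top,                  # strict cuts
                                docking_threshold = -7, stars_threshold = 5)
lipinski_violations(MW = 320, logP = 2.1, HBD = 2, HBA = 5)
#> [1] 0
```

A thin CLI over the same functions (subcommands `simulate`, `train`,
`predict`, `screen`) ships in `inst/scripts/cpifuse-cli.R`.

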