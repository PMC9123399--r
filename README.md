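# nlpnn

Binary classifiers for small clinical tabular datasets, built around two
estimators:

* **NLPNN** — a *network-limited polynomial neural network*: a feedforward
  feature constructor whose nodes are polynomial functions of the input
  features, with the network depth and per-layer width capped in advance
  (default: each layer holds at most d+1 nodes), topped by an
  L2-regularized hinge-loss linear readout. It targets *feature hiding* —
  the situation where the diagnostic signal lives in interactions and
  powers of the recorded covariates rather than in the covariates
  themselves — while the caps keep it from overfitting small samples.
* **AEPNN** — an *attention-empowered* boosting ensemble of NLPNNs for
  class-imbalanced data: multiplicative sample weights are shifted onto
  misdiagnosed cases after every round, so later networks concentrate on
  the minority (sick) class that an accuracy-optimal single model tends to
  wave through.

## The model

Labels are y ∈ {−1, +1} with +1 the sick case. Layer 1 is a truncated
orthogonal basis (SVD) of the augmented data matrix `[1 X]`; layer m is
built from Hadamard products of layer-(m−1) and layer-1 columns, greedily
selected by orthogonal least squares against the labels and rescaled to
norm √n. On top of the feature stack `F = [F¹ … Fᵐ]` the readout solves

    min_ν  Σᵢ wᵢ max(0, 1 − yᵢ (b + Fᵢ·ν))  +  λ ‖ν‖₂

by seeded mini-batch SGD, for every layer cutoff m and every λ in a grid
(default 10⁻³ … 10¹); the pair with the best validation accuracy on a
stratified 20% carve-out wins and is refit on the full training data.

AEPNN runs up to `L_max` boosting rounds: round l fits an NLPNN under the
current sample-weight distribution, gets the vote weight
αₗ = ½ ln((1−εₗ)/εₗ) from its weighted training error εₗ, and updates the
weights by Dₗ₊₁ ∝ Dₗ exp(−αₗ y hₗ(x)). The prediction is
sign(Σ αₗ hₗ(x)). `select_iterations()` picks the round maximizing recall
growth minus accuracy drop, the trade that matters in screening.

The package also ships the evaluation metrics (accuracy, specificity,
precision, recall, F1, G-mean = √(recall·specificity), midrank AUC), the
CSV experimental protocol (zero-fill of missing cells, stratified 8:2
split), a seeded synthetic-data generator with polynomial decision
boundaries and controllable imbalance, JSON model serialization, and a
small CLI.

## Worked example

Fit a single network on an easy synthetic dataset (degree-2 truth, mild
1:4 imbalance) and evaluate on a held-out split:

```r
library(nlpnn)

gen   <- synth_generate(synth_spec(n = 600, d = 3, degree = 2,
                                   imbalance_ratio = 4, label_noise = 0.02,
                                   seed = 42))
parts <- split_table(gen$table, split_spec(test_fraction = 0.2, seed = 42))
fit   <- nlpnn(parts$train, nlpnn_config(seed = 42))
fit
#> nlpnn_model: 2 layers (widths 4,4); readout uses layers 1..2, lambda = 0.01
evaluate_model(fit, parts$test)
#> metric_report:
#>   accuracy     0.9750
#>   specificity  1.0000
#>   precision    1.0000
#>   recall       0.8800
#>   f1           0.9362
#>   g_mean       0.9381
#>   auc          0.9781
```

The fitted network kept two layers of four nodes each (the d+1 = 4 cap)
and chose λ = 0.01 on its internal validation carve-out. On the 120
held-out samples it recovers 88% of the sick cases while keeping every
healthy case (specificity 1.0); G-mean summarizes the two as 0.938.

Where boosting earns its keep is heavily imbalanced, feature-rich data.
On a 1:12 dataset with 40 features (the shape of the diabetes registries
that motivate the method), a single accuracy-optimal NLPNN detects *no*
sick cases at all, and the reweighted ensemble buys back 41% of them for
an 11-point accuracy cost (about 5 minutes to run):

```r
gen   <- synth_generate(synth_spec(n = 2000, d = 40, degree = 2,
                                   imbalance_ratio = 12, label_noise = 0.02,
                                   seed = 23))
parts <- split_table(gen$table, split_spec(test_fraction = 0.2, seed = 23))
cfg    <- nlpnn_config(seed = 23)
single <- nlpnn(parts$train, cfg)
evaluate_model(single, parts$test)
#> NLPNN test: accuracy 0.9025 recall 0.0000 G-mean 0.0000
ens <- aepnn(parts$train, L_max = 10, config = cfg, val_table = parts$test)
sel <- select_iterations(ens$history)
evaluate_model(ens, parts$test, L = sel)
#> AEPNN(4/5) test: accuracy 0.7900 recall 0.4103 G-mean 0.5839
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "nlpnn_cli.R", package = "nlpnn"))')" \
    simulate --n 500 --d 4 --degree 2 --imbalance 12 --seed 1 --out data.csv
Rscript .../nlpnn_cli.R fit --data data.csv --label label --positive 1 \
    --seed 1 --boost 10 --out-model model.json --out-metrics metrics.json
```

Every run writes a manifest echoing the resolved parameters and seeds;
exit codes are 0/1/2 for ok / usage error / runtime error.

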