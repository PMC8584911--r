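# mrcae — multi-run concrete autoencoders for stable feature selection

`mrcae` selects a small, stable subset of **actual** features (genes,
lncRNAs, ...) from a high-dimensional expression matrix, without labels.
It is built for the situation where latent reductions (PCA, standard
autoencoders) compress well but return pseudo-features nobody can validate
at the bench, and where a single run of a stochastic selector returns a
different feature set every time.

## The method

A **concrete autoencoder (CAE)** replaces the encoder with a selection
layer of `k` relaxed-categorical nodes.  Node `j` holds logits
`α_j ∈ ℝ^n` and, per sample, computes Gumbel-softmax weights

    w_j = softmax((α_j + g) / T),   s_j = ⟨w_j, x⟩,   g ~ Gumbel(0,1)^n

while an MLP decoder (two 300-node hidden layers, leaky ReLU 0.1, 10%
dropout) reconstructs all `n` inputs from the `k` mixtures; training
minimizes mean squared reconstruction error (Adam, lr 0.002, 300 epochs)
as the temperature `T` anneals exponentially from 10 to 0.1.  As `T → 0`
each node commits to a single real input feature; the *mean–max
probability* of the selection layer tracks that commitment and the
per-epoch characteristic trace (temperature, mean–max probability, train
and validation loss) is kept on every run.

Because single runs are stochastic, **mrCAE** trains `R` independent runs,
counts for every feature the number of runs that selected it, and ranks
features by that cross-run frequency; the Top-N *stable* features are the
output.  The package also ships the surrounding harness: stratified
k-fold linear-SVM scoring of any feature set, feature-set overlap
summaries, random-search tuning of epochs/learning rate, and a per-feature
prognostic screen — median split at each feature's expression, log-rank
test `χ² = (O_A−E_A)²/E_A + (O_B−E_B)²/E_B`, hazard ratio
`HR = (O_A/E_A)/(O_B/E_B)`, flagged prognostic when `p ≤ 0.05` and
`HR ≠ 1`.  A synthetic-data generator with planted driver features and a
planted survival effect makes the whole pipeline testable with no
download.

## Worked example

```r
library(mrcae)

sim <- generateExpression(syntheticSpec(seed = 1))   # 500 x 200, 10 drivers
cfg <- caeConfig(k = 10)

runs <- runMrCAE(sim$expr, cfg, n_runs = 10, base_seed = 1000,
                 labels = sim$labels)
ft   <- frequencyTable(runs)
top  <- topStableFeatures(ft, 10)
top
#> StableFeatureSet: top 10 of 10 requested (ties: frequency desc, feature_id asc)
#>  feature_id frequency
#>       F0043        10
#>       F0079        10
#>       F0146        10
#>       F0022         8
#>       ...

length(intersect(rankedFeatures(top)$feature_id, sim$drivers))
#> [1] 10       # all 10 planted drivers in the stable Top-10

runs[[1]]
#> CAERun (seed 1001): 8/10 unique features selected
#>   final epoch 300: T = 0.1, mean-max prob = 0.966, train loss = 0.01692, val loss = 0.02643
#>   held-out hard-selection MSE: 0.02639

scoreFeatureSet(sim$expr, sim$labels,
                rankedFeatures(top)$feature_id, n_folds = 5, seed = 1)
#> 5-fold linear SVM (C = 1): accuracy 0.998, macro precision 0.998, recall 0.998, F1 0.998

spec <- syntheticSpec(seed = 1)
clin <- generateSurvival(spec,
          exprValues(sim$expr)[, sim$drivers[spec$survival_driver]])
scr <- prognosticScreen(sim$expr, clin, rankedFeatures(top)$feature_id)
subset(scr, prognostic, c(feature_id, p_value, hazard_ratio))
#>   feature_id      p_value hazard_ratio
#> 2      F0079 7.612313e-03    0.7694204
#> 3      F0146 7.600022e-12    0.5148390
#> 6      F0109 2.041205e-03    0.7390111
#> 7      F0157 4.386825e-02    1.2189969
#> 9      F0100 1.285765e-02    0.7828484
```

(The numbers above are from this exact script; run-to-run they are
reproduced bit-for-bit given the seeds.)  A command-line front end wraps
the same functions:

```sh
mrcae simulate  --out-prefix sim/ --seed 1
mrcae normalize --in X.tsv --out Xn.tsv
mrcae train     --in sim/expression.tsv --labels sim/labels.tsv \
                --k 100 --epochs 300 --lr 0.002 --seed 7 --out runs/run7.json
mrcae aggregate --runs 'runs/*.json' --top 10,20,40 --out stable.tsv
mrcae evaluate  --in sim/expression.tsv --labels sim/labels.tsv \
                --features stable.tsv --folds 5 --out metrics.tsv
mrcae survival  --in sim/expression.tsv --clinical sim/clinical.tsv \
                --features stable.tsv --out prognostic.tsv
```

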