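---
title: "Stable unsupervised feature selection with multi-run concrete autoencoders"
author: "mrcae package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable unsupervised feature selection with multi-run concrete autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Expression cohorts routinely measure tens of thousands of transcripts (for
instance ~12,000 lncRNAs across a pan-cancer cohort) of which a small subset
carries most of the usable signal.  Latent-space reductions (PCA, standard
autoencoders) compress well but return *pseudo-features* — combinations of
all inputs — which cannot be taken back to the bench.  A concrete autoencoder
(CAE) instead learns to pick `k` *actual* input features: its encoder is a
selection layer of `k` relaxed-categorical nodes, and its decoder is judged
by how well those `k` features reconstruct the entire input space.

CAE selection is stochastic: two runs on the same data return overlapping
but different feature sets.  The multi-run extension (mrCAE) embraces this:
run the CAE `R` times, count for each feature the number of runs that
selected it, and rank features by this cross-run frequency.  High-frequency
("stable") features are the output.  The package implements the CAE, the
multi-run aggregation, the evaluation harness used to compare feature sets
(stratified k-fold linear-SVM classification and set overlaps), and a
median-split Kaplan–Meier / log-rank screen for prognostic value — plus a
synthetic-data generator that makes every stage testable offline.

## The selection layer

Node `j` of the selection layer holds a logit vector
$\alpha_j \in \mathbb{R}^n$.  On the forward pass for one sample $x$, each
node draws standard Gumbel noise $g$ and computes relaxed one-hot weights

$$ w_{ji} \;=\; \frac{\exp\{(\alpha_{ji} + g_{ji})/T\}}
   {\sum_{i'} \exp\{(\alpha_{ji'} + g_{ji'})/T\}},
\qquad s_j = \sum_i w_{ji}\, x_i , $$

so the node's output $s_j$ is a noisy convex mixture of inputs,
differentiable in $\alpha$.  The temperature $T$ follows the exponential
schedule $T(e) = T_0 (T_E/T_0)^{e/E}$ (defaults $T_0 = 10$, $T_E = 0.1$ over
$E = 300$ epochs): early training explores near-uniform mixtures, late
training is near-argmax so each node commits to one feature.  At the end,
node `j` selects $\arg\max_i \alpha_{ji}$, and the *mean–max probability* —
the mean over nodes of $\max_i \mathrm{softmax}(\alpha_j)_i$ — diagnoses
convergence: values near 1 mean every node has committed.  The per-epoch
trace of temperature, mean–max probability, training loss and validation
loss is the "characteristic plot" of a run (`caeTrace()`).

The decoder is an MLP with two 300-node hidden layers, leaky-ReLU slope
0.1 and 10% dropout, linear output of size `n`; the loss is mean squared
reconstruction error over all `n` features.  Training uses Adam at learning
rate 0.002 on an 80/20 split, stratified by class labels when available.
Validation loss in the trace uses stochastic selection at the current
temperature; the reported `valMSE` uses hard argmax selection, matching
how the selected features will actually be used.

### Choices the reference settings leave open

* **Noise placement.** Gumbel noise is drawn *per sample*, not shared
  across a minibatch.  Shared noise makes all samples in a batch agree on
  which mixture direction to reinforce, which measurably inflates selector
  gradient variance and can stall hardening entirely.
* **Minibatch size (default 16).** Adam's per-coordinate step is bounded by
  the learning rate, so the total distance a logit can travel is roughly
  `lr × number of updates`.  Committing to one feature out of `n` needs a
  logit gap of order `log n` (≈ 7.5 for the softmax maximum to reach 0.9
  over 200 features).  On a 400-sample training split, batch 256 yields only
  600 updates in 300 epochs — hardening is then *arithmetically impossible*
  at the default learning rate, whatever the data.  Batch 16 yields ~7,500
  updates, comparable to the update counts implied by the several-thousand-
  sample cohorts the default epoch/learning-rate settings were tuned on.
  `batchSize` stays configurable; large cohorts can afford larger batches.
* **Optimizer.** Adam with the usual (0.9, 0.999) moments; per-epoch
  temperature updates (the trace is epoch-indexed).
* **Precision.** The training kernel (compiled, RcppArmadillo) works in
  single precision, the convention of neural-network frameworks.  All
  stochastic draws come from R's RNG stream, so `seed` in `caeConfig()`
  reproduces a run bit-for-bit; a plain-R double-precision reference
  implementation of the forward/backward pass is kept in the package and
  the test suite checks the kernel against it (and against finite
  differences) step by step.
* **Duplicate picks.** Two nodes may commit to the same feature; the run
  reports both the per-node picks and the deduplicated set (`|set| ≤ k`).
  Deduplication per run is what makes cross-run frequencies count *runs*,
  not selector nodes.
* **No early stopping.** Runs always complete their configured epochs.

## Multi-run aggregation

`runMrCAE()` trains `n_runs` independent CAEs, run `i` seeded
`base_seed + i`.  Seeds are positional, so the first 10 runs of a 100-run
pool *are* the 10-run system: systems of increasing size can be compared as
nested prefixes without retraining, or built independently from disjoint
base seeds — both readings of "R-run system" are supported.  Runs persist
incrementally to JSON when `out_dir` is given and interrupted jobs resume.

`frequencyTable()` counts run membership; `topStableFeatures()` ranks by
frequency with ties broken by feature ID (ascending) so rankings are
reproducible; `stabilityReport()` tabulates, per system and per Top-N, the
total distinct features and the frequency ranges; `consensusUnion()` merges
Top-N sets from several systems into a final stable list.

## Evaluation harness

`scoreFeatureSet()` restricts the matrix to a feature set and runs
stratified k-fold (default 5) cross-validation with a linear-kernel SVM
(cost 1, via libsvm).  Precision/recall/F1 are macro-averaged: with many
classes of very different sizes, micro averaging nearly duplicates
accuracy.  Fold assignment depends only on the seed, so
`compareFeatureSets()` scores every candidate set on identical folds — a
paired comparison of, say, a stable mrCAE Top-40 set against single-run
selections or externally produced baseline lists (baseline selectors are
deliberately not reimplemented; any feature list plugs in).
`randomSearchTune()` performs the random grid search over epochs and
learning rate (the conventional grids 200–3000 and 0.0005–0.05 are the
sensible inputs) scoring each trial's selection on shared folds.

## Prognostic screen

For each feature, samples with clinical records are split at the median
expression: group A (≤ median, "low") versus group B (> median); ties go
low.  Features that are zero in more than half the cohort are excluded
(`max_zero_fraction = 0.5`; "most samples" read as a strict majority, and
the boundary is inclusive).  The two groups are compared with the standard
log-rank accumulation over distinct event times ($E_g = \sum_t d_t
n_{gt}/n_t$, censored subjects at `t` still at risk at `t`), reported as

$$ \chi^2 = \frac{(O_A - E_A)^2}{E_A} + \frac{(O_B - E_B)^2}{E_B},
\qquad \mathrm{HR} = \frac{O_A/E_A}{O_B/E_B}, $$

with a 1-df chi-square p-value.  The HR is the observed-over-expected rate
ratio derivable from log-rank internals — no proportional-hazards model is
fitted, matching the "hazard rate of A vs hazard rate of B" reading.
HR > 1 means the low-expression group dies faster.  A feature is flagged
prognostic when `p ≤ alpha` (0.05) **and** HR ≠ 1, the literal screening
rule.  Because the literal HR condition is nearly always true in floating
point, `hr_rule = "ci"` offers a stricter variant requiring the 95%
(O−E)/V interval to exclude 1; and because the screen is per-feature and
uncorrected by design, `p_adjust = "BH"` is available but off by default.
Kaplan–Meier curves come from `kmEstimate()` (product-limit, standard tie
conventions).  Both estimators are validated against an independent
survival reference implementation to 1e-8 in the test suite.

## The synthetic generator

`syntheticSpec()` describes a cohort in which ground truth is known by
construction:

* `n_drivers` driver features get class-specific Gaussian means
  (standardized across classes to spread exactly `class_sep`, within-class
  SD 1), so class identity lives in driver space and every driver separates
  the classes with the same effect size — no driver degenerates into a
  near-uninformative feature by draw luck;
* a fraction `dependent_fraction` of the remaining features are *sparse*
  positive mixes of a round-robin-assigned primary driver plus 0–2 random
  secondary drivers, with `N(0, noise_sd)` noise — a balanced regulatory
  fan-out in which every driver is a hub for a comparable share (about a
  dozen) of targets;
* the rest are pure noise; features are shuffled and min–max normalized.

Defaults (500 × 200, 10 drivers, 4 classes, `dependent_fraction` 0.6,
`class_sep` 1.5, `noise_sd` 2) were fixed once, on two grounds.  First,
realism: with driver variance `class_sep² + 1`, `noise_sd = 2` puts
driver–target correlations around 0.6–0.7, the range typical of
regulator–target pairs in expression data, and `class_sep = 1.5` gives
classes that are separable but overlapping.  Second, identifiability: the
planted drivers must actually *be* the reconstruction-optimal subset for
recovery tests to mean anything.  Near-noiseless targets are statistically
interchangeable with their drivers (no selector could, or should, prefer
one), and densely mixed targets are collectively more informative than any
single driver, so a perfectly converged selector provably prefers
surrogates under those designs.  Sparse fan-out with realistic noise makes
each driver strictly better than any of its proxies, which the test suite
verifies with an autoencoder-independent oracle (greedy forward selection
under a linear reconstruction model recovers ≥ 9/10 drivers).

Survival times are exponential with rate
`baseline_hazard * exp(hazard_log_ratio)` above the survival driver's
median and `baseline_hazard` below; censoring is independent uniform with
its upper bound solved in closed form so the expected censored fraction
equals `censor_rate`.  `hazard_log_ratio = 0` yields an exact null for
type-I-error studies.

What the generator does **not** emulate: count-distributed (negative
binomial) expression, zero inflation/dropout, batch effects, correlated
censoring, non-proportional hazards.  Tests passing on this generator show
the algorithms do what they claim under their own assumptions — they are
not evidence about any particular real cohort.

## Numerical and degenerate-input conventions

* Min–max normalization maps constant features to all-zero rather than
  dropping them (dimensionality stays stable; they carry no signal).
  Normalization statistics are computed on the full matrix *before* the
  80/20 split, matching the conventional pipeline order; the mild
  train/test leakage this implies affects reconstruction metrics only, not
  the identity of selected features, but is worth knowing about.
* Concrete weights are computed with max-shifted softmax; uniform draws
  are clamped away from 0 and 1 in float precision before the double-log
  Gumbel transform.
* `topStableFeatures()` breaks frequency ties lexicographically;
  `stratifiedSplit()` keeps at least one training sample per class;
  degenerate median splits and never-expressed features are reported as
  non-analyzable rows of the screen, not errors.
* Log-rank with no events is an error; a group with zero expected events
  reports an infinite HR with an explicit flag.

## Scale of the shipped studies

The package's tests and the acceptance script run the full pipeline at the
default desk scale — 500 × 200 with a 10-run mrCAE pool per base seed for
driver recovery, 5-run pools of `k = 40` for the stability-versus-single-run
comparison, 1,000 null replicates (n = 300) for the screen's type-I error
and 50 replicates for power.  These sizes keep a complete run in the
minutes range on one CPU while leaving every qualitative conclusion
(recovery, stability dominance, convergence, calibration) testable; they
are choices of the package, and all of them scale up through the public
parameters.

## Known limitations

* A single CAE run is a local optimizer; on data whose informative
  features have near-substitutes it recovers *an* informative subset, not
  necessarily the canonical one — that instability is precisely the
  motivation for multi-run aggregation.
* The O/E hazard ratio is a crude estimator compared to a Cox fit; it is
  used because it is the estimator the screening rule describes.
* The screen tests each feature marginally; correlated features yield
  correlated flags, and the uncorrected default trades specificity for
  sensitivity exactly as per-feature `p ≤ 0.05` screens do.
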