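---
title: "Data valuation for high-throughput screens: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data valuation for high-throughput screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(screenval)
```

## The problem

A primary high-throughput screen labels a large compound library once;
a confirmatory screen re-tests a subset of the primary actives. The
resulting tables have three defining features: strong class imbalance
(typically 0.5–5% primary actives), a two-tier label structure
(primary call for everyone, confirmatory call for a few), and a
substantial false-positive fraction among the primary actives. Data
valuation assigns each training compound a score for its influence on
a model trained on the primary data, and those scores turn out to be
useful three times over: to screen libraries more efficiently (active
learning), to nominate false and true positives before confirmatory
chemistry is spent on them (triage), and to thin the inactive majority
class without discarding the samples the model actually learns from
(undersampling).

## The engines and their assumptions

**MVS-A** trains a gradient-boosted tree classifier and treats every
boosting round as a checkpoint. With binary log-loss, the gradient and
Hessian of sample *j* at round *i* are `g = p − y` and `h = p(1 − p)`
evaluated at the model's running prediction before the round. The score
is `Σ_i sqrt(g² + λ h²)` — the minimal-variance-sampling regularized
gradient summed over rounds. The combination rule is isolated in one
function (`mvsa_combine`) so it can be swapped; every boosting round is
used as a checkpoint. Because the ensemble initializes at a constant
probability 0.5 (the backend's base score is pinned there), the round-1
contribution is identical for all samples — a property the tests
exploit. Samples the ensemble keeps struggling with (mislabeled or
contradictory ones) accumulate large scores; that is precisely the
false-positive signature.

**KNN Shapley** computes the exact Shapley value of every training
point under the K-nearest-neighbour utility
`v(S) = (1/K) Σ_{k ≤ min(K,|S|)} 1[y_{α_k(S)} = y_t]`, `v(∅) = 0`,
via the standard descending recursion over points sorted by distance to
a validation compound, averaged over the validation set. The recursion
is exact (the tests verify it against full subset enumeration) and
satisfies efficiency: per validation point the scores sum to the
utility of the full training set. The neighbourhood size is not
prescribed anywhere authoritative; the default is K = 5, exposed as
config. Distances are Euclidean on the feature rows with ties broken by
index. Because the inactive majority would dominate the distance
structure, the majority class is randomly undersampled to a 0.2
minority:majority ratio first; removed samples score 0 and are flagged
rather than silently dropped.

**Leaf influence** approximates leave-one-out retraining of a boosted
ensemble by freezing the tree structures and re-deriving only the leaf
values, `v_L = −η Σg / (Σh + λ)`. Removing sample *j* removes its
gradient statistics from its leaf at every round and the resulting
prediction deltas feed the gradient statistics of subsequent rounds —
a sequential refit that is exact given the frozen structures (for a
single tree it coincides with brute-force frozen-structure retraining
to machine precision, which the tests assert). The sign convention is
positive = removal increases target loss = the sample helps the
target. In self mode the target set is the training actives; note that
the removed sample is then itself part of the target, so a false
positive's removal inflates its *own* target loss and false positives
score high — the same polarity as the other self-importance engines.

**TracIn** trains a feed-forward network (dense 512-unit input layer
plus three 512-unit hidden layers, ELU activations, dropout 0.5 on the
hidden layers, L2 1e-4 on every dense layer, sigmoid output, binary
cross-entropy, Adam at 1e-3) and snapshots the parameters at epochs 30,
60 and 90. Influence is computed from per-sample loss gradients with
respect to the last two layers' weights only; the factored form of
dense-layer gradients (outer products of activations and deltas) lets
all inner products be computed without materializing per-sample
gradient matrices. Self-importance sums squared gradient norms over
checkpoints; test-importance sums learning-rate-weighted dot products
with the mean validation gradient; pos restricts the validation set to
actives. The checkpoint weight η is the optimizer's base learning rate,
constant at 1e-3, since no per-step schedule is prescribed. Gradient
evaluation at a checkpoint runs in inference mode (no dropout); the
regularization term is shared across samples and excluded from
per-sample gradients.

**DVRL** learns per-sample selection probabilities with a
reinforcement signal. The value estimator maps (features, label)
through two 100-unit hidden layers; the *marginal information* — the
absolute error |y − ŷ| of a baseline predictor trained once on the
full training set — enters just before a 10-unit combining layer, as
in the reference architecture. Each iteration draws several Bernoulli
selection masks from the estimator's probabilities, fits a boosted-tree
predictor on every selected subset, and scores validation ROC-AUC; the
rollout-mean reward serves as the baseline of a score-function
(REINFORCE) gradient. Three numerical choices matter and are worth
stating plainly. First, the multi-rollout baseline: with a single
rollout the per-iteration advantage is almost pure noise at desk scale
and the estimator cannot learn. Second, an exploration penalty pushes
the mean selection probability back inside [0.1, 0.9]; without it the
optimizer discovers that selecting everything is never penalized and
all probabilities saturate at the upper clip. Third, leaky rectified
activations with a small positive bias initialization keep the narrow
combining layer from dying (a dead 10-unit layer makes the output
constant and unrecoverable). Probabilities are clipped to
[1e-3, 1−1e-3] so sampling never degenerates. Defaults are
reduced-scale (200 iterations, batch 256) relative to the full-scale
setting (1000 × 5000), which is configurable but not the desk default.
A caveat that the recovery test made explicit: DVRL can only value
samples whose inclusion measurably moves the reward. Its planted-noise
test therefore uses a small training set, moderate class separation
and a deep per-rollout predictor, a regime where including mislabeled
samples demonstrably lowers validation AUC; with a large, easily
separable training set the reward is insensitive and no estimator —
at any scale — could recover the noise from it.

## Splits, orientation, and the workflows

The validation split is the 10% of compounds with the *highest*
activity scores (ties broken by ascending record index, so the split
is deterministic). This mirrors the curation convention for screens
whose engines need a held-out set: the top-score stratum is the most
activity-enriched slice available without confirmatory data. Scores
outside [0, 100] are min–max rescaled per dataset at load time.
Duplicate structures (after canonicalization) are merged keeping the
first occurrence, with labels aggregated by maximum so an active call
survives the merge — the curation source does not state its rule, and
keep-first is the least surprising.

Triage orientation is data, not code: each engine/mode pair declares
in a config table whether a high score marks a false positive
(`engine_orientation()`), so adding an engine never silently inverts a
ranking. Nominee sets are the extreme `round(0.10 · n_actives)` of the
ranking at each end; the fraction is configurable but capped below 0.5
so the sets cannot overlap. Metrics are computed only over
confirmatory-labeled actives (unlabeled actives keep their ranks but
are skipped), with "top 10%" rather than "top 10 compounds" as the
default precision cutoff — both phrasings circulate; `k` accepts a
count as well. The enrichment-factor denominator uses
`ceiling(fraction · N)`.

Active-learning batches are a fixed absolute size, `round(0.015 · n)`
of the whole library, recomputed from the full library size at every
step; the initial batch is stratified to preserve the library's
active:inactive ratio. The importance strategy scores the labeled pool
with a self-mode engine (default MVS-A), fits a Gaussian-process
regressor (radial-basis kernel, unscaled binary inputs) from features
to importance, and screens the compounds with the highest predicted
importance — greedy-on-importance; no other acquisition rules are in
scope. The wall time of each step is recorded in the in-memory trace
but deliberately left out of the trace CSV so that rerunning a
campaign with the same seed yields byte-identical files.

Undersampling computes importance once on the full training set and
then removes `round(0.05 · n_train)` inactives per step (ties broken
by index), up to 95% removed or until the inactive pool is exhausted
(flagged). Performance is measured as average precision on a held-out
split after retraining the classifier at every step. For this
evaluation the package uses a stratified random holdout rather than
the top-score split: a top-score holdout is dominated by actives, and
average precision on it saturates regardless of policy.

## What the generator emulates — and what it does not

`simulate_screen` is feature-first: compounds are binary vectors drawn
around latent cluster prototypes (per-bit flip probability 0.05 by
default), true actives populate two designated active clusters, and
planted false positives are uniform random bit vectors — structurally
isolated from every prototype — that nevertheless carry a primary
active label and an active-like score. Activity scores are Gaussian:
actives around 60 (sd 20), inactives around 35 (sd 15), clipped to
[0, 100]. The spreads were chosen once so that the classes overlap the
way primary-screen readouts do: the top-score validation split then
captures high scorers of *both* classes and a workable share of
actives remains in training. False positives draw their scores from
the active distribution, so the score benchmark cannot identify them —
only their structural isolation and label inconsistency can, which is
exactly the signal the self-importance engines exploit.

What the generator does not emulate: real chemistry (attached SMILES,
when requested, come from a fixed fixture list and are unrelated to
the features), assay-specific artifact mechanisms (aggregation,
fluorescence interference), activity cliffs, and correlated
plate/batch effects. Consequently the structural-alert filter
benchmark is uninformative on synthetic screens — alerts on arbitrary
fixture structures are noise with respect to the planted false
positives — and passing triage tests shows that the engines recover
*planted* label noise with structural isolation, not that they would
match any particular alert catalog on real PubChem data.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately modest sizes chosen to keep
the full suite in the minutes range while preserving every qualitative
contrast: triage on n = 3000 screens with 256-bit features (10
seeds), active learning on n = 5000 libraries with 1024-bit features
(10 seeds, 5 steps), undersampling on n = 1000 with 128-bit features
and a 50-round classifier (10 seeds), MVS-A leave-one-out comparison
at n = 500 with 20 boosting rounds, and the exhaustive Shapley oracle
at N ≤ 8. The leave-one-out oracle for MVS-A uses *self-loss* deltas
(the change in a sample's own loss when it is removed): total-set loss
deltas are dominated by the retraining jitter of the stochastic tree
backend and carry no per-sample signal.

Other fixed numerical choices: boosted-tree backends run
single-threaded with the base score pinned at 0.5; all randomness
derives from one integer seed per run through fixed offsets, so every
trace, score vector and output file is reproducible bitwise;
descriptor matrices impute non-finite entries to the column median
(flagged when a column is more than half non-finite); the descriptor
list is pinned at 208 entries (the toolkit registry minus two
overflow-prone information-content indices); fingerprints are hashed
binary vectors, not counts.

## Known limitations

Engine scores depend on the backend: MVS-A and leaf-influence values
reflect this package's boosted-tree implementation (xgboost histogram
trees), not any specific other library's, although the oracle tests
pin the math given the structures. TracIn and DVRL are exact
implementations of their small-network architectures, trained in plain
R; they are practical at desk scale (thousands of compounds) but not
tuned for six-figure libraries. DVRL remains the weakest detector, in
line with how sensitive reinforcement-based valuation is to reward
noise. The leaf-influence LOO loop is quadratic in training size times
rounds and is the slowest engine; it is intended for the
moderate-sized screens the workflows target.
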