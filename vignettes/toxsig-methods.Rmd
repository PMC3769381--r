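---
title: "Deriving and evaluating carcinogenicity signatures with toxsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating carcinogenicity signatures with toxsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`toxsig` derives multi-gene mRNA signatures from short-term liver
toxicogenomics studies and uses them to predict whether a compound behaves
like a genotoxic carcinogen (GC), a nongenotoxic carcinogen (NGC) or a
non-carcinogen (NC). This vignette documents the model, its assumptions,
the tunable parameters and their defaults, the synthetic benchmark, and the
numerical decisions taken where the methodology leaves room.

## The data model

The raw material is a normalized log2 expression matrix (probesets x
samples) with per-sample annotations: treatment group id, compound,
vehicle, dose, sex, dosing duration (3 or 14 days) and carcinogenicity
class (GC / NGC / NC / UNDEF / CONTROL). The unit of analysis throughout is
the **treatment group** — all replicate animals sharing compound, dose, sex
and duration — represented by the vector of mean log2 fold changes of all
probesets against the time-matched vehicle control:

```
fc(g, p) = mean log2 treated(g, p) - mean log2 control(vehicle(g), duration(g), p)
```

Controls are matched on vehicle *and* duration; both sexes are retained as
separate groups but pooled into one training set per duration. The two
durations are modeled strictly separately and never pooled, because early
defense responses (day 3) and adaptive changes (day 14) are biologically
distinct regimes. Compounds dosed at two levels contribute two independent
treatment groups with the same class label. Compounds with undefined class
(UNDEF) are excluded from all training and only classified post hoc.

Working at the group level rather than the animal level is a modeling
choice: the group mean is the quantity the fold-change representation
defines, and it is what the prediction heatmaps and projections describe.
Per-animal modeling would require a different noise model and is out of
scope.

## Stage 1: bootstrap ensemble signature extraction

For one binary task (C vs NC, GC vs NGC, GC vs NC, NGC vs NC) and duration:

1. **Bootstraps.** `n_bootstraps = 25` class-stratified subsamples, each
   containing `in_bag_fraction = 0.90` of the training groups, drawn
   *without* replacement so that the complementary 10% forms a genuine
   out-of-bag set. The per-class in-bag counts are the floored 90% shares;
   the rounding remainder goes preferentially to classes that still retain
   an out-of-bag member.
2. **Selectors.** On each bootstrap (features z-scored on the in-bag
   groups) each selector produces a total ranking of all probesets:
   - `GOLUB`: absolute signal-to-noise ratio |mu+ - mu-| / (sd+ + sd-);
   - `SVM`: absolute weights of a linear soft-margin SVM (`cost = 1`);
   - `SVM_RFE`: recursive elimination — drop the floor-half of the
     remaining features per refit while more than 10 remain, then one at a
     time; the reversed elimination order is the ranking;
   - `PAM`: nearest-shrunken-centroid scores max_k |d_kj| with
     d_kj = (centroid_kj - overall_j) / (m_k (s_j + s0)), s0 the median
     pooled SD, shrinkage threshold `delta = 0` by default (`delta` is
     exposed, since ranking at a tuned threshold is a defensible variant);
   - `PCA` / `PLSDA`: absolute loadings of the first component (for a
     single ±1-coded response the first PLS weight vector is proportional
     to the feature–label covariance and is computed in closed form).
   The default ensemble is {GOLUB, SVM, SVM_RFE, PAM}; the reduced
   {SVM, SVM_RFE} and the {PCA, PLSDA} variants are selectable.
3. **Out-of-bag ROC.** At 10 candidate sizes {2, 5, 10, 15, 20, 30, 40,
   60, 80, 100}, each ranking's top features train the selector's natural
   decision rule (linear SVM for the SVM selectors, shrunken centroids for
   PAM, weighted voting for the filter/loading selectors) on the in-bag
   groups; the rank-based AUC on the out-of-bag groups is averaged over
   bootstraps. Bootstraps whose out-of-bag set contains one class are
   excluded from the mean.
4. **Optimal size.** A cubic smoothing spline (smoothing chosen by
   generalized cross-validation) is fitted to mean AUC vs size and the
   argmax over the integer grid is taken. Ties — including perfectly flat
   curves — resolve to the smallest size (parsimony); fewer than 4 finite
   points fall back to the raw argmax; no finite point at all (possible at
   very small scale, below) falls back to the smallest size.
5. **Stability.** Per size, the mean pairwise Kuncheva index
   KI = (rP - k^2)/(k(P - k)) of the 25 top-k subsets. KI is 1 for
   identical subsets, -1 for disjoint half-universe subsets, and 0 in
   expectation for independent draws; these anchors pin the formula down
   and are asserted in the tests.
6. **Consensus.** Every feature's rank positions are summed over all
   n x m rankings (full rankings, not top-k membership, which is what a
   rank sum over total orderings means) and features are sorted by
   ascending rank sum, ties broken by probeset index. The consensus size
   defaults to the rounded median of the per-selector spline optima —
   robust to one selector's degenerate curve — and can be fixed via
   `consensus_size`, which also allows skipping the out-of-bag evaluation
   when only the signature is needed.

## Stage 2: classification with rescaled confidences

Signature fold changes are z-scored with mean and n−1 SD estimated on the
training groups only; a zero-variance training feature gets SD := 1 (the
feature becomes constantly 0, with a warning) so that applying a signature
never aborts on a flat gene. Six classifiers emit a confidence in [0, 1]
for the positive class:

| classifier | confidence |
|---|---|
| linear SVM | decision value d through 1/(1+e^(−d)) |
| k-NN | fraction of positively labeled nearest neighbors |
| PAM | shrunken-centroid posterior with class priors |
| naive Bayes | Gaussian posterior (features are continuous z-scores) |
| random forest | fraction of trees voting positive |
| weighted voting | strength v = (V+ − V−)/(V+ + V−) through (v+1)/2 |

The logistic map for SVM and the affine map for weighted voting are chosen
as the canonical monotone maps onto [0, 1] from each score's natural
domain; all AUC-based results are invariant to any monotone rescaling, so
this choice only affects the readability of the confidence heatmaps.
Weighted voting weights each feature by its signed signal-to-noise ratio
around the midpoint of the class means; an all-zero vote abstains at 0.5.

Hyperparameters are tuned by inner cross-validated AUC over fixed grids:
SVM cost {0.01, 0.1, 1, 10, 100}; k-NN k {1, 3, 5} (Euclidean distance,
distance ties broken by training index); PAM delta over 10 evenly spaced
values spanning the data-driven shrinkage path; random forest 500 trees
with features-per-split in {sqrt(P), P/3}. Ties in inner AUC resolve to the
smaller (more regularized) grid value. Naive Bayes and weighted voting have
no tuned parameters.

## Evaluation

`nested_cv()` runs stratified nested 3x3 cross-validation. When the
signature source is Stage 1, the **full** Stage-1 pipeline reruns inside
every outer training fold, so feature selection never sees the outer test
groups; the test suite asserts this by deleting a fold's test profiles and
checking the signature is unchanged. Fold assignment defaults to
`by_compound`: all treatment groups of one compound (both sexes, all
doses) share an outer fold, preventing a compound from informing its own
prediction through its other groups; `by_group` assignment is available
since group-level folding is also defensible. Fixed published signatures
are evaluated with the same harness (`evaluate_fixed_signature()`), with
absent probesets dropped under a warning.

Undefined compounds are scored by every classifier and called per compound
by majority vote; confidences of exactly 0.5 abstain and a tied or empty
vote is reported as `"ambiguous"`, never silently resolved.
`pca_project_groups()` provides the 2-D principal-component coordinates of
group profiles restricted to a signature, for class-separation displays.
`auc()` is the rank-based (Mann–Whitney) statistic with ties counted 1/2,
verified against exhaustive pair enumeration.

## The synthetic benchmark

`synthetic_design()` / `generate_synthetic_dataset()` emulate the
motivating study design: 14 compounds — 3 GC (one dosed at two levels),
3 NGC, 4 NC, 3 UNDEF — each dosed in both sexes for 3 and 14 days with 6
replicates per treatment group and time-matched vehicle controls (corn oil
or carboxymethyl cellulose) per vehicle, sex and duration. Probeset
baselines are Normal(8, 1) log2 units with Normal(0, 0.5) replicate noise.
Three disjoint planted sets of 20 probesets carry the signal:
carcinogen-shared, GC-specific and NGC-specific effects of
`effect_size = 2` replicate SDs (1.0 log2 unit), with a fixed random sign
per probeset. GC compounds shift shared+GC-specific, NGC compounds
shared+NGC-specific, NC nothing; each UNDEF compound follows an explicit
GC-like or NGC-like generative regime so its correct call is known. Day-3
effects are attenuated by a factor 0.6, encoding the empirical pattern
that 14-day data discriminate more reliably than 3-day data as a
generative knob rather than a claim. A random 5% of probesets carry a
±0.5 log2 sex-specific baseline shift in males, a nuisance that survives
into fold changes because controls pool both sexes.

Two realistic properties of this design are worth knowing when reading
test results. First, vehicles correlate with classes (as in the real study
design, where genotoxic compounds were corn-oil dosed and most
non-carcinogens CMC-dosed), and all profiles sharing a vehicle share their
control-group noise; a classifier can therefore perform slightly above
chance even with zero planted effect. Second, with 22 defined-class
groups a *single* label permutation can align with the planted signal by
chance, so the permutation-null check averages over 10 permutations rather
than trusting one. The generator does **not** simulate probe-level
physics, batch effects, normalization artifacts, or correlated gene
modules — passing tests show the pipeline recovers planted structure
under Gaussian noise at study scale, not that real-data accuracies are
reproduced.

One scale consequence: for GC vs NGC there are only 14 defined groups, so
a 90% subsample leaves a single out-of-bag group and every out-of-bag AUC
is undefined; the optimum-size estimate then falls back to the smallest
candidate size with a logged message. This is inherent to 90%
subsampling at that class size, not a defect of the estimator; consensus
signatures and stability are unaffected.

Test and acceptance runs use the generator defaults (2000 probesets,
3 x 20 planted features, effect 2 SD, seed 0) for parameter-recovery
checks, and reduced scales (300 probesets, 5–10 bootstraps) for
structural checks.

## Degenerate inputs and tie-breaks, collected

- Ranking ties: stable order by probeset index everywhere, so all rankers
  are deterministic; stochastic classifiers are seeded explicitly.
- Golub / weighted-voting denominators of 0: replaced by the median
  positive denominator (flat features score 0 rather than infinity).
- PAM s0 of 0 (perfectly separated toy data): replaced by the smallest
  positive pooled SD, or 1 if none, keeping discriminants finite.
- Zero-variance features at z-scoring: SD := 1 with a warning.
- Single-class out-of-bag sets: that bootstrap's AUC is excluded and
  logged.
- Flat ROC curves: smallest size (parsimony).
- Exactly balanced votes, equidistant points, empty vote sets: 0.5 /
  "ambiguous", reported explicitly.

## Limitations

- Binary tasks only; the four pairwise tasks are run separately.
- Confidence maps are monotone surrogates, not calibrated probabilities.
- The consensus-size policy (median of spline optima) is a heuristic; the
  published-signature sizes suggest task-specific choices are also
  reasonable, which is why `consensus_size` is exposed.
- Real-study accuracies depend on the actual microarray data and
  unpublished seeds; this package reproduces the methodology and verifies
  it on synthetic ground truth, and evaluates any externally supplied
  signature through the same harness.
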