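---
title: "Methods: correlation-aware naive Bayes for drug-combination screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-aware naive Bayes for drug-combination screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combiNB)
```

combiNB treats effective-combination prediction as binary classification of
drug *pairs*. This vignette records the model, its assumptions, the
numerical conventions, and the design decisions that were genuinely open —
so that anyone extending the package knows which choices are principled and
which are conventions that could defensibly have gone another way.

## Pair representation

A drug is a sparse integer vector over one feature category: 0/1 for
targets, pathways, metabolic enzymes and transporters, 0/1/2 for
dose-coded side effects (none / reported at low dose / reported at high
dose). A pair is encoded as the **elementwise sum** of its two drugs'
vectors, giving entries 0–2 (0–4 for side effects). Summation keeps the
distinction between "one drug has the annotation" and "both do", which a
logical OR would erase; it is symmetric, so unordered pairs are
well-defined. Pairs are canonicalized as `(min_id, max_id)` so that
membership tests against the positive set are unambiguous, and pairs
missing a drug in the feature table are dropped rather than imputed —
absence of annotation is not evidence of a zero profile.

Negative (non-effective) pairs are sampled either from the drugs occurring
in positive pairs (strategy N1) or from a whole catalogue (N2), always
excluding known positives and self-pairs, without replacement, under an
explicit seed. Where a protocol repeats the negative draw (ratio sweeps,
y-randomization), each repetition draws independently under a derived
sub-seed; nothing in the method requires the draws to be coupled across
repetitions.

## Ellipse feature screening

Screening binarizes every pair feature (any nonzero code becomes 1) and
computes, per feature, `p1` — the frequency of 1 among negatives — and
`p2` — the frequency among all labeled pairs. Under class homogeneity
`p2 ≈ p1`; the null scatter of `(p1, p2 − p1)` is widest at `p1 = 0.5` and
collapses at the endpoints, which the screening ellipse

$$\frac{(p_1 - 0.5)^2}{0.5^2} + \frac{(p_2 - p_1)^2}{a^2} = 1$$

captures geometrically: `a` sets the significance level, and informative
features fall outside the ellipse. The level `a` itself is not canonical,
so the package ranks features by the per-feature **critical level**
`a* = |p2 − p1| / sqrt(1 − (p1 − 0.5)²/0.25)` — the smallest `a` whose
ellipse still contains the point — and keeps the top `m` (default 30).
Any fixed-`a` rule is the special case "keep everything with `a* > a`",
so `m` is the single tuning knob. Conventions: `a* = 0` when
`p2 = p1`; `a* = ∞` when `p1 ∈ {0, 1}` with a nonzero shift (the ellipse
has no height there, so any shift is infinitely surprising); ties in `a*`
break toward the lower feature index. A permutation utility
(`calibrate_ellipse_null()`) estimates the null distribution of `a*`
empirically for users who want an explicit level rather than a rank cut.

Two open points were settled as follows. `p2` is computed on **labeled**
samples only — the unlabeled pool has no labels to mix in, and using it
would conflate the screening statistic with the pool's unknown
composition. And screening binarizes dose codes while the classifier keeps
them: binarization makes `p1`, `p2` genuine Bernoulli frequencies, whereas
the classifier's rank transform can exploit the full 0–4 gradation. Both
choices are arguments, not laws, and both are configurable at the call
sites.

The mRMR baseline (`select_by_mrmr()`) is the mutual-information-difference
greedy scheme on discrete values with plug-in estimates, deterministic with
index tie-breaks. It is included purely as the conventional comparator.

## The improved naive Bayes model

The classifier is a Gaussian discriminant in a whitened feature space,
constructed in three steps.

**Normal transformation.** Each feature is mapped to normal scores by the
rank-based inverse normal transform with the Blom 3/8 offset,
`x → Φ⁻¹((r − 3/8)/(n + 1/4))`, average ranks for ties. The original
formulation only says the features are transformed to normality without
naming a transform; the rank-based INT is the standard distribution-free
choice and is the only reasonable one for sum-coded features supported on
three to five values. The transform is fitted on **all** samples — labeled
plus unlabeled — because marginal shape carries no label information, and
held-out samples are mapped through monotone interpolation of the fitted
knots with clipping beyond the training range (a new pair cannot outrank
the extremes the map was built from). Constant columns carry no rank
information; they are flagged and mapped to 0.

**Correlation eigenbasis.** The correlation matrix `R` of the transformed
features, again over labeled ∪ unlabeled samples, is eigendecomposed:
`R = P Λ Pᵀ`. This is where the naive-Bayes independence assumption is
relaxed: the discriminant operates on decorrelated projections rather than
raw features. Feeding the pool into `R` is the semi-supervised heart of
the method — correlation structure is estimable from unlabeled candidate
pairs, which in realistic screens outnumber labeled ones several-fold.
With no pool, `R` falls back to the labeled samples alone.

**Class moments and scores.** With per-class means/SDs `μk, σk` of the
transformed features and overall-sample means/SDs `μ, σ` (computed over
labeled ∪ unlabeled, matching the basis), each sample `x̂` yields

$$\beta = \left(\tfrac{\hat x - \mu}{\sigma}\right) P, \qquad
  \gamma_k = \left(\tfrac{\hat x - \mu_k}{\sigma_k}\right) P,$$

$$H_k = \ln P(C_k) - \sum_i \left( \frac{\gamma_{ki}^2}{2\lambda_i}
        + \ln \sigma_{ki} \right), \qquad
  L = \sum_i \frac{\beta_i^2 - \gamma_{ki}^2}{\lambda_i}.$$

`argmax_k H_k` is the prediction when priors are meaningful (empirical
class frequencies by default); `L` is the prior-free membership score,
thresholded on a ROC curve over a labeled calibration set — by default the
threshold maximizing Youden's J, with closest-to-(0, 1) as an alternative,
candidate thresholds being the observed scores so the rule is
translation-equivariant. Exact ties in `H` break toward the non-effective
class: for a screening tool a false "effective" call is the costlier
error.

Two formulation ambiguities are resolved verbatim rather than
"improved upon". First, `γk` reuses the *overall* eigenbasis `P` and the
*overall* eigenvalues `λ` even though it standardizes by class — a full
per-class whitening would use class-specific bases, but that is a
different model. Second, `H_k` carries no `½ ln λ_i` term, so it is not
exactly a Gaussian log-density in the rotated space; the term is
class-constant under the shared basis and therefore cancels in the argmax
anyway. One reading note: the source formulation prints the
class-subscripted moment symbols twice; the second set is read as the
overall-sample moments, which is the only reading consistent with the
unsubscripted `μ, σ` appearing in the `β` projection.

**Reduction to Gaussian naive Bayes.** Forcing `R = I` gives `λ_i = 1`,
`P = I`, and `H_k` collapses termwise to the independent-Gaussian
log-posterior. The package exposes this as `correlation = FALSE` and the
test suite verifies decision-for-decision agreement with an independent
Gaussian-NB implementation — this ablation is also the package's
"naive Bayes with the same information" comparator.

**Regularization.** `H_k` and `L` divide by `λ` and take `ln σ`, so
degenerate directions would produce infinities: eigenvalues are floored at
`1e-6 · n_features` (then rescaled to restore `Σλ = n_features`, the trace
of a correlation matrix) and standard deviations at `1e-6`. The floors are
far below any eigenvalue or SD arising from non-degenerate data; they only
guard rank-deficient corners.

## Baselines

The conventional comparators run through the same interface
(`classifier_spec()` / `train_baseline()` / `predict_classifier()`), with
the reference hyperparameters as defaults: categorical naive Bayes with
Laplace smoothing 0 (a zero-count category contributes `-Inf`
log-likelihood; a sample impossible under both classes falls back to the
prior argmax, tie to non-effective), k-nearest neighbours with `k = 5` and
minimum vote `l = 2` (doubt is assigned non-effective, keeping the output
hard-binary for metric computation), and an RBF SVM with `C = 10`,
`γ = 0.1`, using the decision-function value as score. The SVM delegates
to e1071 and the KNN to the class package, whose vote semantics match the
`l` rule natively; the categorical NB is implemented in the package
because library implementations replace zero-count probabilities with a
small threshold, changing the Laplace-0 contract. Baselines consume the
same selected, sum-coded features as the improved model; whether the
original experiments binarized for the baselines is unrecorded, and the
choice is configurable.

## Evaluation protocol

Metrics follow the standard confusion-matrix definitions, with display
rounding at four decimals, half-up (0.69565 → 0.6957). Degenerate
denominators: a ratio whose denominator vanishes because the corresponding
error count is zero is 1; the MCC is 0 when its denominator vanishes. The
ROC sweeps thresholds over the unique scores and integrates by trapezoid,
which equals the Mann–Whitney concordant-pair statistic with half credit
for ties (asserted to 1e-12 in the tests). LOOCV refits **feature
selection inside every fold**; selecting once on the full data would leak
the held-out label into the feature ranking and inflate every downstream
number. Folds whose training part becomes unusable (a class vanishing at
small n) are skipped with a warning rather than failing the run.
Train/test splits take `floor(n × 0.75)` training samples uniformly,
without stratification — the independent-test protocol is a single seeded
split, with repetition exposed through the seed rather than averaged
implicitly. `recover_confusion_from_metrics()` inverts printed
(accuracy, recall, precision) triples back to integer confusion matrices
by exhaustive search, which is how the package cross-checks published
four-decimal tables for internal consistency.

y-randomization refits the entire pipeline — selection and classifier —
on label-permuted data. Permutation preserves class counts, so the
original-vs-shuffled contrast isolates the signal carried by the
label-feature association.

## The synthetic generators

`generate_drug_universe()` emulates the statistical shape of real per-drug
annotation tables: sparse Bernoulli features (default prevalences drawn
from U(0.05, 0.25), the sparsity range typical of curated annotation
matrices) thresholded from a latent Gaussian with block structure (blocks
of 10 features sharing a latent factor, default within-block latent
correlation 0.3) — annotations cluster (one pathway implies related
targets), and the copula gives exact marginal control under correlation.
Side-effect categories cut the latent variable twice, splitting each
feature's prevalence evenly between low- and high-dose codes. Presets
expose the real per-category feature dimensionalities (targets 681/787,
pathways 255/263, enzymes 135/146, transporters 76/86, side effects
3005/3889 for the N1/N2 constructions) while the default 200 keeps test
runs fast.

`generate_pair_study()` plants the class signal **at the pair level**: on
each informative feature (10 by default, spread evenly across the feature
range) the positive rows' presence indicator is resampled to frequency
`q⁻ + effect_size`, where `q⁻` is the realized frequency among the
sampled negatives. The pair is the unit of analysis, so planting at pair
level makes `effect_size` directly interpretable against the screening
statistic: the gap `p2 − p1` is `effect_size/2` at a 1:1 ratio, and the
generator's recovery is verified empirically in the tests (±0.05 at ≥1000
pairs). The default `effect_size = 0.3` with 200 positive pairs puts the
planted features clearly above the `O(n^{-1/2})` null noise without making
the problem trivial — roughly the regime where screening is useful at all.

What the pair generator does *not* emulate: real marginal statistics of
specific databases beyond sparsity and block correlation, identifier
structure, or between-category dependence. Tests passing on these studies
show the machinery is correct and well-calibrated under its own
assumptions; they do not certify performance levels on any real
extraction.

`generate_gaussian_study()` draws from the classifier's own generative
regime — per-class correlated Gaussians (within-block correlation 0.6)
with the mean shift (±0.3) on **one feature per block**. The sparse
placement is deliberate: when the shift is dense within a block it aligns
with the block's principal axis and a diagonal model is already
near-optimal, whereas a sparse shift lets the whitened model use the null
block-mates to cancel the shared-factor noise — the precise mechanism by
which modelling correlation helps. This is the study used for the
improved-vs-naive comparison; pair-sum encoded binary data decorrelates
substantially, and on such weakly correlated studies the two models are
close, which the benchmark numbers reflect honestly.

## Problem sizes and runtime envelope

The shipped tests and the acceptance script use study sizes chosen to make
sampling noise small relative to the asserted margins while keeping a full
run in minutes on one core: 400 labeled pairs (200 positive) with a
300-pair unlabeled pool for LOOCV benchmarks and y-randomization, 25
replicates of the 100-sample Gaussian study for the correlation-model win
rate, 50 seeded studies for the screening recovery rate, and 100 seeds for
the large-n screening consistency check. All randomness flows through
explicit seeds; every generated artifact is a deterministic function of
its configuration.

## Known limitations

* Binary task only; the score formulas extend to more classes but nothing
  in the package exercises that.
* The correlation matrix is estimated once from the pooled sample; if the
  two classes have genuinely different correlation structures the shared
  basis misspecifies both (inherent to the formulation, noted above).
* Real-database coverage questions — identifier mapping, category overlap
  of actual drug sets — are out of scope; `coverage_summary()` reports
  per-category pair coverage for tables the user supplies.
* The KNN and SVM baselines inherit the numerical behaviour of the class
  and e1071 packages (e.g. distance-tie handling), which is documented but
  not re-implemented.
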