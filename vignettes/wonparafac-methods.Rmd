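---
title: "Methods: weighted orthogonal non-negative PARAFAC and its downstream pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted orthogonal non-negative PARAFAC and its downstream pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wonparafac)
```

This vignette records the model, the conventions the implementation
fixes where the method leaves room, and the reasoning behind each
choice. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data cube

Per-data-type genes × samples matrices are aligned on the intersection
of their identifiers and stacked into a non-negative three-way array.
Expression is standardized per gene (mean 0, SD 1); copy number is
reduced to loss/neutral/gain via `cn <= loss_threshold` → −1 and
`cn > gain_threshold` → +1 (strict gain, non-strict loss; defaults 1 and
5); mutations are 0/1. Mixed-sign layers are split on sign into two
non-negative layers, so a typical cube has layers GE(+), GE(−), CN(+),
CN(−), MT.

Conventions fixed here:

* **SD convention**: population SD (divide by n), so small worked
  examples are exactly reproducible; `sd_type = "sample"` switches.
  Zero-variance genes become all-zero rows and are flagged rather than
  dropped, preserving alignment.
* **Order of preprocessing**: standardize/ternarize first, then
  sign-split.
* **Second-cohort statistics**: an independent cohort is standardized
  with its own per-gene means/SDs (passed via `ref_means`/`ref_sds`),
  matching how a xenograft panel is processed relative to a cell-line
  panel. This is also the step that removes cohort-level per-gene batch
  offsets before projection.
* **Genes missing from one data type** can be zero-filled by the caller
  to preserve alignment (see the cube tests for the pattern).

## The factorization

With unfoldings X(G) (cd × g), X(C) (gd × c), X(D) (gc × d) and
Khatri-Rao products Y_CD, Y_GD, Y_GC, the model minimizes, mode by mode,

$$\min_{F \ge 0} \sum_{i,j} W(i,j)\,\big( Y F^\top(i,j) - X(i,j)\big)^2$$

by multiplicative updates of the form F ← F ⊙ numerator/denominator,
where the numerator is (W ⊙ X)ᵀY and the denominator
(Wᵀ ⊙ (F Yᵀ)) Y. Because updates are multiplicative, non-negativity is
preserved exactly, and each update does not increase its own weighted
objective.

* **Weight tensor.** One scalar per data-type layer, 1/‖X_d‖²_F,
  constant over the layer's slab. The motivating description ("data
  types with less variance obtain high weights", a weight tensor the
  size of X) admits only this per-layer reading, which we implement;
  `compute_weights(cube, layer_weights = ...)` allows any override.
* **Orthogonality.** For the gene mode only, the gradient is projected
  onto the Stiefel manifold (GᵀG = I), yielding the alternative
  denominator (Wᵀ ⊙ (G Y_CDᵀ)) X(G) G. A mixing weight `w` blends the
  two denominators: `w = 0` is the plain weighted update, `w = 1` the
  fully constrained one, default `w = 0.1`. The constraint discourages a
  gene from loading on many factors unless data types genuinely share
  the pattern. Monotonicity of the objective is a theorem-backed
  property only for the unconstrained update; the test suite asserts it
  empirically for w ∈ {0, 0.1} and treats larger w as heuristic.
* **Numerics.** Denominators are floored at 1e-12; entries whose
  numerator and denominator both vanish stay 0 (zero-locking, standard
  NMF practice). Convergence: relative objective change below `tol`
  (default 1e-6) or `max_iter` (default 500) sweeps in the fixed order
  gene → sample → layer. Learning-rate exponent fixed at 1.
* **Initialization.** `"random"`: i.i.d. uniform factors rescaled so the
  initial reconstruction matches the cube's Frobenius norm, seeded.
  `"eigen"`: elementwise absolute values of each mode unfolding's
  leading right singular vectors (computed from the small mode-Gram
  matrix), deterministic up to the sign ambiguity the absolute value
  resolves; columns beyond a mode's dimension (the layer mode whenever
  k > d) are seeded uniform draws scaled to the singular columns' mean
  norm.
* **Normalization.** Performed once after convergence (the update rules
  assume unnormalized factors): each factor column is rescaled to unit
  l2 norm, the per-factor scale is the product of the three removed
  norms, and factors are sorted by decreasing scale with stable
  tie-breaking by original index. All-zero factors get scale 0, sort
  last, and are flagged.
* **Unfolding convention.** In all three unfoldings the layer index
  varies slowest and the remaining paired mode fastest; `khatri_rao(A, B)`
  puts its first argument's index slowest. Any self-consistent
  convention gives the same model; consistency is enforced by tests
  linking `unfold()`, `khatri_rao()` and the reconstruction.

## Choosing the number of factors

Each candidate rank is fitted from the deterministic singular-vector
initialization and scored by

* **AIC** in the Gaussian profile form n·ln(RSS/n) + 2p with n the
  number of cube entries and p = k(g + c + d). The method's description
  names AIC without a formula; this is the standard least-squares form,
  and both counts are overridable (`n_obs`, `n_par`).
* **Redundancy**: the mean cosine similarity over all unordered column
  pairs of Y_GD, focusing on dependency between captured alterations.

"Low AIC and low cosine" is not an algorithm, so the scan's explicit
stand-in rule is: smallest rank whose AIC is within a 1% band of the
minimum, restricted to ranks with mean cosine below 0.5 (the guardrail
is ignored if nothing satisfies it). Gaussian AIC with this parameter
count can prefer ranks slightly above a planted rank on noisy cubes; the
acceptance test asserts the majority behaviour, not per-seed exactness.

## Factor annotation

**CSEA.** For a category T of size n_T with factor loadings c,
ES = √n_T · Σ_{i∈T}(c_i − m)/(n_T σ), with m and σ the mean and
population SD of *all* loadings. The description of the score leaves the
index set of "n" ambiguous; n = n_T is the only reading under which ES
is approximately N(0, 1) under random membership (finite-population
variance (N − n_T)/(N − 1)), which the stated right-tailed normal test
presupposes. The literal all-samples variant is available via
`n_convention = "all"`. P-values are right-tailed normal, FDR is
Benjamini–Hochberg within factor, and FDR < 0.2 flags significance.

**GSEA.** Every gene's expression is regressed on all k sample-factor
loadings jointly (ordinary least squares with intercept; a tiny-ridge
fallback handles rank-deficient designs, and `simple = TRUE` switches to
univariate slopes since the source description is ambiguous between the
two). Per factor, the coefficient-ranked gene list is scored with the
weighted Kolmogorov–Smirnov running sum at weight exponent 1. The null
distribution permutes *samples* of the expression matrix and propagates
each permutation through the regression; because the per-gene
coefficient is a fixed linear functional E·h of the samples, a
permutation of E's columns equals a permutation of h, making each null
draw one matrix–vector product. NES divides ES by the mean |null ES| of
its sign per set; FDR follows the original GSEA's pooled-null
positive/negative-side computation, per factor. Note that under a
complete null this FDR — like any valid FDR — calls far *fewer* than 20%
of sets at the 0.2 threshold (it bounds the false-call rate from above);
the calibration tests therefore assert uniform permutation p-values and
a call rate at or below nominal, not equal to it.

## Drug response

Per compound, an elastic net (glmnet) of AUC on factor loadings or raw
features. Choices: mixing parameter α = 0.5 (unstated in the source;
config-exposed and recorded), solver-default predictor standardization
(factor scales differ), per-compound dropping of missing responses,
λ at minimum CV loss. Fold memberships are a pure function of
(n, folds, seed) — `cv_folds()` — so factor-based and raw-based models
share byte-identical partitions, the stated fairness requirement.
Performance is the Pearson r between concatenated out-of-fold
predictions and observations from a nested double-loop CV (outer folds
held out entirely, inner CV tunes λ).

A caveat this package documents deliberately: the pooled out-of-fold
correlation is *negatively biased under the null*. With no signal the
held-out prediction is essentially the training-fold mean, and
m₋ₖ − m = −(mₖ − m)/(K − 1) gives E[r] ≈ −√((K−1)/n); the bias is
conservative (it cannot manufacture skill) and shrinks only as 1/√n.
The acceptance suite asserts the idealized zero-centred behaviour and
therefore carries one expected failure; the test suite's own null checks
bound |r| accordingly.

Factor contributions are mean |βⱼ·xᵢⱼ| over samples normalized to sum 1
over selected predictors (no formula is given in the source; this is the
natural magnitude decomposition of the linear predictor).
`sensitivity_partition()` takes the union of the top-5 factors by |β|,
treats negative coefficients as sensitivity factors (AUC convention:
lower = more sensitive), and assigns each sample by comparing summed
loadings, ties going to the configured side (default "sensitive",
logged).

## Cohort projection and separation

`project_cohort()` freezes G and D and iterates only the sample-mode
multiplicative update for the new cohort's loading matrix P, from a
seeded uniform initialization scaled to the cohort's norm. The projection
objective is the plain (unit-weight) Frobenius norm: the stated
projection objective is unweighted, and with unit weights the
multiplicative update's monotonicity applies to exactly that objective
(a `weights` argument restores the weighted variant). The cohort cube
must match the model's gene and layer axes exactly — no silent
subsetting. Per-sample explained variation 1 − ‖resid‖²/‖fiber‖² is
compared against a permuted baseline in which gene and sample indices
are permuted independently within each layer (per-layer independence is
our choice, to destroy cross-layer structure as well).

`tissue_association()` is the share of a sample's total loading carried
by a tissue-linked factor set. `fisher_criterion()` is
|m₁ − m₂|²/(s₁² + s₂²) with population variances and, for 2-D points,
total variance = trace of the per-group covariance; it is exactly
invariant under rotation, translation and uniform scaling.
`embedding_separation()` treats the 2-D embedding as an external
contract — any `(X, seed) → n × 2` function, deterministic given its
seed. The default, `random_projection_embedding()`, is a seeded Gaussian
random linear projection: a simple stochastic embedding that satisfies
the contract; a t-SNE wrapper can be substituted without changing any
other code. The separation conclusions are reported as the full
distribution over (default) 100 repeats, never a single embedding.

## Synthetic data: what it emulates, and what it does not

`sim_spec()` defaults describe the study conditions used throughout the
tests: 120 genes × 80 samples × 5 layers with 6 planted factors, 50%
sparse gene-factor columns, layer scales (5, 5, 1, 1, 0.5) emulating the
variance imbalance between expression-like and mutation-like data types,
additive Gaussian noise of SD 0.1 clipped at zero (multiplicative noise
behind a flag), 2 factors supported on ≥ 2 layers (cis-effect
analogues), 4 tissue blocks with block-elevated sample loadings, and
drug-response coefficients β = (−2, 1, 0, …) so the first factor is a
sensitivity factor. Every generator is a pure function of its spec, and
every data type is guaranteed signal from at least one factor. Smaller
cubes used in individual tests (e.g. 40 × 30 × 4 for recovery, 30 × 20 ×
5 for monotonicity) are chosen so the whole suite runs in about a
minute; the acceptance script uses the full default scale.

`sim_paired_cohort()` draws a new cohort from the same block structure
under the frozen planted G and D. Its optional batch effect adds fixed
half-normal per-(gene, layer) offsets, restricted to features with zero
planted signal: batch artefacts concentrated in signal-free features are
the realistic regime and lie outside the planted factor span. Even so,
*estimated* factors absorb a little of any non-negative offset through
small spurious entries, so factor-space cohort separation is reduced
rather than eliminated — the acceptance script reports both medians
without asserting their order, while the separation contract itself is
tested on controlled feature matrices.

What the generators do **not** emulate: real expression covariance,
linkage or mutational signatures, dose-response curve shapes, or
platform-specific noise. Passing tests therefore demonstrate that the
algorithms do what they claim under the assumed structure, not that the
biology of any particular dataset will be recovered.

## Known limitations

* CP factorizations are non-convex; different seeds can reach different
  local optima. The deterministic singular-vector initialization makes
  runs reproducible, not globally optimal.
* The AIC parameter count ignores the scale indeterminacy within each
  factor triple; the rank-selection rule is an explicit stand-in for a
  qualitative criterion.
* The orthogonality-mixed update (w near 1) has no monotonicity
  guarantee.
* Pooled out-of-fold correlation is negatively biased under the null
  (see above); comparisons between predictor sets on shared partitions
  remain fair.
* Missing data are handled only through the weight tensor and
  per-compound response dropping, not by explicit masking.
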