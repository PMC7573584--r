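---
title: "Wing morphometrics for mosquito identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing morphometrics for mosquito identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

This vignette documents the statistical models behind `wingmorph`, the
choices made where the methods literature leaves options open, and what the
synthetic-data generator does and does not emulate.

## The scientific problem

Mosquito surveillance needs cheap, reliable species identification.
Morphological keys fail on damaged specimens and DNA barcoding is costly,
so landmark-based wing geometric morphometrics is an attractive middle
ground: wing vein junctions are homologous, easy to photograph, and their
relative positions are species-informative. The package reimplements the
full analysis chain used in that setting — superimposition, size and
allometry statistics, discriminant classification with cross-validation,
distance-based trees, observer-error and landmark-sampling diagnostics, and
a compact COI likelihood stage used to cross-check morphometric clusters
against molecular ones.

## Superimposition

A configuration is `k = 18` landmarks in 2-D. Centroid size
`CS = sqrt(sum_i ||x_i - centroid||^2)` carries all size information;
generalized Procrustes analysis (GPA) removes translation (centering),
size (rescaling to CS = 1) and rotation, leaving shape.

Numerical choices:

* **Rotations only, never reflections.** All wings come from one body
  side, so chirality is fixed; allowing reflections would merge distinct
  shapes. The 2-D optimal rotation has the closed form
  `theta = atan2(sum(x_t × x_r), sum(x_t · x_r))`.
* **Iteration.** The consensus starts at the first configuration; each
  round rotates every configuration onto the consensus and recomputes it
  (re-centered, rescaled to unit CS). Convergence is declared when the
  consensus moves less than `tol = 1e-8` (root summed squared change),
  with a cap of 100 iterations; non-convergence warns and flags the result
  rather than failing. Typical datasets converge in well under ten rounds.
* **Canonical orientation.** A GPA solution is only defined up to a global
  rotation (it inherits the arbitrary orientation of the starting
  configuration). The final solution is therefore rotated so the consensus
  principal axis lies along x with positive x-skew, making the output
  invariant — to numerical precision — under any similarity transform of
  any input configuration. Configurations with a rotationally degenerate
  (near-isotropic) consensus are left in the frame found by the iteration.
* **Tangent projection.** Downstream statistics use the orthogonal
  projection of the aligned coordinates onto the tangent plane to shape
  space at the consensus. For wing-scale variation the projection moves
  points by a negligible amount (the aligned coordinates can be used
  directly via `tangent_projection(..., project = FALSE)` for sensitivity
  analysis), but it makes the linear multivariate machinery exactly valid.

A caveat recorded as a property rather than hidden: the chord (partial
Procrustes) distance between two shapes equals the sum of their distances
to the GPA consensus only up to third-order curvature terms, so the
pairwise-vs-consensus consistency checks in the test suite use nearby
shapes and an absolute tolerance of 1e-6.

## Size statistics and allometry

Centroid size is compared across species with ordinary one-way ANOVA and
all pairwise two-sample pooled-variance t-tests under Bonferroni adjustment
(`p_adj = min(1, m p)` over the `m = g(g-1)/2` comparisons).

Allometry is tested by multivariate regression of all shape columns on log
centroid size. The effect size is `R^2 = SS_model / SS_total` summed over
columns, the statistic is the pseudo-F
`(SS_model / 1) / (SS_resid / (n - 2))`, and significance comes from fully
randomizing the specimen-to-size assignment — the simplest residual
randomization null for a single regressor, which is exact under
exchangeability. With the conventional 500 permutations and the add-one
convention the smallest attainable p is `1/501 ≈ 0.002`. Allometric
residuals are *not* removed before classification (size variation is
itself informative for identification); residualization is available as a
sensitivity analysis by regressing the shape matrix on log CS before
`fit_lda()`.

Procrustes variance (disparity) of a group divides by `n`, not `n - 1`,
matching the convention of the morphometrics tools this mirrors; the
unbiased denominator is a switch.

## Classification

Raw shape variables are rank-deficient (2k coordinates carry at most
2k − 4 dimensions), so a principal-component projection retains components
with eigenvalues above `1e-10` of the largest — an isometry on the observed
data — additionally capped at `n − g − 1` components so the pooled
within-group covariance stays invertible with few specimens. LDA uses
group-frequency-proportional priors by default (the behavior of the
standard R discriminant tooling; uniform priors are a flag — with species
samples of 14–30 the choice matters only at the margin). Exact posterior
ties resolve to the lexicographically lowest label.

Leave-one-out cross-validation refits the model from scratch on every fold
(`n ≈ 500` makes rank-one update tricks unnecessary and refits
unambiguous). Neither the GPA nor the reduction basis is recomputed per
fold, mirroring the study pipeline this emulates (one superimposition,
then cross-validated LDA); the leakage is negligible for shape data but is
stated rather than hidden, and a strict protocol can be built by re-running
`generalized_procrustes()` per fold.

CVA axes come from the eigen-decomposition of `W^-1 B` computed via
whitening; Mahalanobis distances between group means use the pooled
within-group covariance (denominator `n − g`). On resampled data
(bootstrap) duplicated specimens can make `W` ill conditioned, so the CVA
subspace shrinks until the smallest eigenvalue exceeds `1e-9` of the
largest.

## Trees and bootstrap

Neighbor joining is the Saitou–Nei algorithm; Q-criterion ties break on the
lowest index pair and negative branch lengths clamp to zero without
redistribution (the simplest defensible convention). NJ is exact on
additive matrices, which the tests exploit as an oracle. Bootstrap support
resamples *specimens within species* — the distance matrix lives on species
means, so resampling specimens is what propagates sampling variance into
the tree; replicates whose distance matrix cannot be built are skipped with
an adjusted denominator. Supports are percentages of replicate trees
containing the same leaf bipartition, with splits keyed by the side not
containing the alphabetically first leaf so rooting is irrelevant.

## Landmark sampling curve (LaSEC)

Each iteration draws a random landmark order and grows nested subsets from
3 to k; each subset is re-superimposed from the raw coordinates and the
fidelity of its shape space is the Pearson correlation between the
vectorized lower triangles of the inter-specimen tangent distance matrices
(subset vs full scheme). This fit metric is a deliberate reimplementation
choice — the published sampling-curve function is not restated in the
sources this follows — and is flagged as such; nested subsets (rather than
independent draws per size) match the "sampling curve" construction and
reduce Monte-Carlo variance. Degenerate subsets (e.g. collinear triples)
cause the whole iteration to be redrawn, with the count reported. The fit
at size k is a self-comparison and is 1 by construction.

## COI likelihood stage

The substitution models are JC69, K80 and HKY85, optionally with discrete
Gamma rate variation (4 categories, category rates equal to the means of
the quantile bins of Gamma(alpha, alpha) — the Yang mean-of-bin variant, so
rates average exactly 1). Rate matrices are scaled to one expected
substitution per unit branch length; base frequencies for HKY85 are
empirical counts, not ML-optimized. Likelihoods use Felsenstein pruning
over compressed site patterns with per-node underflow rescaling; gaps and
N are fully ambiguous, so all-gap columns contribute zero log-likelihood.

Branch lengths are optimized coordinate-wise by Brent search on
`[1e-8, 10]` (log scale) using cached inside/outside partial likelihoods;
the per-edge likelihood as a function of branch length reduces, through the
spectral decomposition of the rate matrix, to
`sum_m e^{lambda_m t} (U'W)_m (VD)_m` per site pattern, so a sweep costs
two tree traversals plus cheap 1-D searches. Sweeps repeat until the gain
drops below `1e-4`, and each sweep's proposal is accepted only if the full
log-likelihood improves (step-halving otherwise), so the optimizer is
monotone. `kappa` is searched on `[0.05, 100]` and the Gamma shape on
`[0.02, 50]`, both in log space, alternating with branch-length sweeps.

Model selection fits six candidates ({JC69, K80, HKY85} × {+G, plain}) on
one fixed NJ topology and ranks by `AIC = 2p − 2 lnL`, with parameters
counted as branch lengths + kappa (1) + alpha (1) + empirical frequencies
(3 for HKY85). Six models are a deliberate compact subset of the usual
24-model batteries: enough to distinguish frequency, ts/tv and
rate-variation structure. The ML search starts from NJ on pairwise ML
distances and applies nearest-neighbor interchanges; candidates are ranked
with a cheap two-sweep branch-length pass and the final topology gets a
full optimization (reverting to the start if, exceptionally, no
improvement survives). The bootstrap resamples columns and reruns the NNI
step from the full-data topology — the standard reduced-effort scheme.

## The synthetic generator

The generator stands in for digitized wing photographs, which cannot be
re-digitized at desk scale. Its defaults *are* the emulated study design:
19 species in 5 genera with the published per-species specimen counts
(502 wings total) and sampling-site counts, 18 landmarks, 3 specimens per
species re-measured by 4 observers.

* **Mean structure.** Genus means displace the wing template by isotropic
  Gaussian offsets of scale `2*delta` per coordinate and species means add
  scale `delta`, so genera separate more than species. `delta = 8 *
  sigma_w` produces the strong-separation regime in which reclassification
  is near-perfect — the analogue of the emulated study's headline
  accuracies.
* **Noise calibration.** `sigma_w = 0.0055` shape units per coordinate,
  with shared per-(species, site) offsets of scale `sigma_w / 2`, was
  chosen once so that the mean per-species Procrustes variance after GPA
  (which removes 4 of the 36 coordinate degrees of freedom) lands near
  0.0012 — the magnitude reported for real mosquito wings. Observer noise
  defaults to `sigma_w / 2`, placing observer variance well below species
  variance, again matching the field observation.
* **Size and allometry.** Species median centroid sizes are log-spaced
  over 2.4–4.4 (arbitrary units, a factor ≈ 1.8 between extremes, as seen
  between the largest and smallest species) and assigned to species in
  seeded random order; within-species sizes are lognormal with CV 8%.
  The allometric effect adds `beta * log(CS / species median)` along one
  common unit direction in shape space, `beta = 0.07`. At the full design
  the *whole-sample* allometry R² is dominated by chance between-species
  shape–size association (2–10% across seeds — real datasets report values
  in this range); `beta` governs the within-species signal that the
  permutation-power checks exercise.
* **Confusable pairs.** `merge_pair` forces one species mean to within a
  stated Procrustes distance (default `sigma_w`) of another, reproducing
  the situation of sibling species whose wings are essentially
  indistinguishable: that pair then dominates the off-diagonal of the
  species confusion matrix while every other species stays highly
  identifiable.
* **What is not emulated.** Pixel-level digitization, correlated or
  anisotropic landmark noise, within-wing covariance structure from vein
  geometry, missing landmarks, and sex or seasonal effects. Passing tests
  on this generator therefore demonstrates correctness of the estimators
  under the stated model, not robustness to every property of real wing
  photographs.
* Sequences evolve along a user-supplied tree under the chosen model with
  per-site continuous Gamma rates; the study-analogue script uses a seeded
  coalescent species tree with AT-rich HKY+G parameters typical of insect
  mitochondrial COI.

All randomness in a simulation flows from one seed, and every generator
output embeds its design, so a dataset is reproducible from its metadata.

## Problem sizes used in validation

The test suite exercises the full 19-species design at `n = 20` specimens
per species over 50 seeds for the classification-recovery checks, 500 null
simulations for the permutation-calibration check, 200 random additive
trees for NJ, and 50 replicates each (20 taxa × 550 bp, and 4 taxa × 550
bp) for the model-selection and topology-recovery checks. These sizes were
chosen so each property is measured with useful Monte-Carlo precision while
the whole suite stays convenient to run routinely.

## Known limitations

* 2-D landmarks only; no semilandmarks, sliding, or missing-landmark
  estimation.
* The permutation test covers a single regressor (log CS); no
  mixed-model or nested designs for the observer analysis — the observer
  report is descriptive, in line with its role as a data-quality check.
* The ML search explores NNI space only and, like all hill climbers, can
  stop at a local optimum; the NJ start and the monotone optimizer make it
  deterministic and reproducible rather than exhaustive.
* GTR-family and invariant-sites models, and Bayesian inference, are out
  of scope; the candidate set is the compact six-model battery described
  above.
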