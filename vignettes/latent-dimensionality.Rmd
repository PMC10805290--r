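---
title: "Latent dimensionality and encoding performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent dimensionality and encoding performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodim)
```

## The scientific question

Encoding models map a candidate representation (for example, activations of
a deep network layer) to measured neural responses with cross-validated
linear regression, and score the mapping by held-out prediction accuracy. A
geometric property of the candidate representation — its *latent
dimensionality* — turns out to matter for this score: representations that
spread their variance over many principal components can cover more of the
dimensions a neural population happens to encode, and they also generalize
better to novel object categories. This package implements the machinery
needed to study that claim quantitatively on fully synthetic data:
dimensionality estimation, a subspace-alignment simulation, a neural
encoding pipeline with noise-ceiling normalization, prototype transfer, and
projection-distance concentration analysis.

## Effective dimensionality

The package's dimensionality statistic is the participation ratio of an
eigenspectrum $\lambda_1 \ge \lambda_2 \ge \dots$:

$$ \mathrm{ED} = \frac{\left(\sum_i \lambda_i\right)^2}{\sum_i \lambda_i^2}. $$

It is continuous, scale-invariant, permutation-invariant, and lies between 1
(all variance on one component) and the number of nonzero eigenvalues (flat
spectrum). `compute_eigenspectrum()` obtains $\lambda$ from the singular
value decomposition of column-centered data with the $n-1$ sample-covariance
denominator; an explicit covariance eigendecomposition is used as an oracle
in the tests. When fewer than `n_channels` components are estimable the
spectrum is zero-padded to the channel count, a convention that leaves ED
unchanged.

```{r}
effective_dimensionality(c(1, 1, 1))
effective_dimensionality(c(4, 2, 1))
```

For convolutional feature maps, ED is computed on *channel* covariance:
`global_average_pool()` collapses the spatial grid first, so the statistic
reflects the diversity of encoded features rather than spatial smoothness. A
flattened, pooling-free path is available by reshaping the array yourself
and passing the matrix directly; the pooled analysis is the default because
channel covariance is what the dimensionality-vs-performance question is
about.

For a truncated power-law spectrum $\lambda_i = i^{-\alpha}$,
`power_law_ed(alpha, n)` evaluates the participation ratio analytically,
which gives every generator-based test an exact target. `fit_power_law()`
estimates $\alpha$ as the negative least-squares slope of
$\log \lambda_i$ on $\log i$; $\lambda_i \propto 1/i$ — the reference decay
at which representations are maximally expressive while still smooth —
yields exponent 1 exactly.

## Synthetic data generators

The generators define the study conditions for every downstream analysis;
all are seeded and bit-reproducible.

* `gen_power_law_features(n, p, alpha, seed)` draws zero-mean Gaussian
  features whose population eigenvalues are $i^{-\alpha}$ over a random
  orthonormal basis. The empirical spectrum converges to the target (the
  tests require < 10% relative error on the top 10 eigenvalues at
  $n = 50p$).
* `gen_neural_responses(features, n_units, k, snr, n_repeats, seed)` builds
  each unit as a fixed random linear readout of the top $k$ principal
  directions of the features plus independent Gaussian noise per repeat,
  scaled per unit so that signal variance / single-repeat noise variance
  equals `snr`. This makes two closed forms exact in expectation: split-half
  reliability of two repeats is $\mathrm{snr}/(\mathrm{snr}+1)$, and a
  full-rank regression of single-repeat responses on the features attains
  held-out $R^2 \to \mathrm{snr}/(\mathrm{snr}+1)$.
* `gen_category_clouds(M, n, d, D, radius, separation, seed)` places $M$
  class centroids in a single random $d$-dimensional subspace of the
  $D$-dimensional feature space, scaled so the *expected* pairwise centroid
  distance equals `separation`, and fills each class with samples uniform in
  a $d$-ball of the given radius (direction $\times$ radius
  $\cdot U^{1/d}$, the exact construction). All classes share one latent
  subspace: this is what makes `latent_dim` the representation's latent
  dimensionality (the ED of the generated cloud is of order $d$) and puts
  the between-class readout directions inside the span of the class clouds,
  so the concentration benefit of high $d$ — projections of order
  $\mathrm{radius}/\sqrt{d}$ — actually reaches the classifier. With
  independent per-class subspaces the readouts are almost orthogonal to the
  clouds and the dimensionality benefit is diluted away; we verified this
  variant and rejected it.
* `gen_feature_maps()` supplies Gaussian 4-way arrays for pooling tests.

What the generators deliberately do **not** emulate: receptive-field
structure, correlated (non-Gaussian) noise, stimulus-dependent noise, and
the architecture-specific spectral quirks of real networks. Passing tests
on these generators validate the *machinery* and the geometric claims under
idealized conditions; they are not evidence about any particular network or
cortical area.

## The subspace-alignment simulation

`simulate_encoding_experiment()` realizes the conceptual model behind the
dimensionality question. Observations are drawn from a *natural* subspace
(64 of 128 ambient dimensions, spectrum $i^{-0.1}$, i.e. slowly decaying).
Two smaller subspaces are carved out of it:

* the *ecological* subspace (default 32 dimensions, spectrum $i^{-0.5}$)
  stands in for what a neural population encodes;
* the *model* subspace, whose spectrum exponent controls its ED
  (reported analytically via `power_law_ed()`).

*Alignment pressure* (AP $\in [0,1]$) is operationalized in
`make_aligned_subspace()` as column-wise interpolation between an
independently drawn orthonormal basis (AP = 0) and the ecological basis
(AP = 1), re-orthonormalized left to right so leading directions retain the
strongest alignment. The choice is verified behaviorally: mean squared
canonical correlation with the reference is 1 at AP = 1, matches the
random-frame Monte-Carlo distribution at AP = 0, and increases monotonically
in between.

Both projections receive isotropic observation noise (`noise_sigma`, default
0.25 against a top spectral weight of 1), which is what gives ED its bite:
model dimensions whose spectral weight falls below the noise floor carry no
usable signal. An ordinary-least-squares encoder (PLS fallback when the
training set cannot support OLS) maps model features to each ecological
dimension; the score is mean held-out $R^2$ across ecological dimensions,
clipped at 0 in summaries with the raw value retained. Noise can instead be
injected into the ambient observations before projection
(`noise_on = "latent"`); the observation-noise default was chosen because it
is the conventional reading of measurement noise, and the alternative is a
flag.

`regime_preset()` encodes the three qualitative regimes with per-regime
geometry:

* **Dimensionality** — AP fixed at 0.3, model subspace as wide as the
  natural space (64), ED swept log-spaced over 2–50. High-ED models span
  more of whatever the ecological subspace occupies, so performance rises
  with ED.
* **Alignment** — model ED fixed at 10 in a 32-dimensional model subspace,
  AP swept over [0, 1]; performance is driven by alignment alone.
* **Joint** — the ED sweep (capped at 28) with AP tied to ED by a
  log-Gaussian bump peaking at ED = 8, yielding an interior optimum. The
  model subspace must be strictly smaller than the natural space here;
  if it spans the natural space, very high-ED models predict well
  regardless of AP and the interior peak disappears — this is why the
  presets differ in `model_dim`.

Training/test sizes default to 500/200 samples; 64 regressors on 200
training samples left OLS overfit-dominated, which motivated the larger
default.

## The neural encoding pipeline

`fit_cv_encoder()` follows the standard electrophysiology recipe: average
trial repeats, shuffle stimuli into contiguous folds from a seed, and fit
partial least squares with 25 latent components under 10-fold
cross-validation (`pls_monkey`), or ordinary least squares under 9 folds
(`ols_fmri`). Per unit, performance is the Pearson correlation between
predicted and held-out responses averaged across folds (the default),
with a concatenated-predictions mode available because the per-fold /
concatenated distinction is ambiguous in common practice; both are shipped
and the per-fold mean is the default. The PLS implementation is NIPALS with
deflation, written here and validated against OLS in the full-rank limit and
against closed-form SNR anchors; fold/unit cells with zero test variance are
dropped from aggregates with a logged count.

`split_half_reliability()` estimates each unit's noise ceiling as the
correlation between stimulus-wise means of two random halves of the
repeats, averaged over `n_splits` splits. The Spearman–Brown correction
$2r/(1+r)$ is applied by default (flagged), since the ceiling is meant to
bound the reliability of the *repeat-averaged* responses being predicted;
the uncorrected value estimates half-data reliability and equals
$\mathrm{snr}/(\mathrm{snr}+1)$ under the generator. The normalized score is
$(\mathrm{median}\, r / \mathrm{median}\, r_{ceil})^2$, a coefficient of
explained variance relative to the ceiling. `pca_reduce()` (default 1000
components from a reference set) keeps encoder size constant across models,
and `rsa_score()` provides the fitting-free representational-similarity
alternative (Spearman correlation of RDM upper triangles).

## Transfer and projection concentration

`monte_carlo_transfer()` implements the novel-category protocol: 50 classes,
50 training and 50 held-out samples per class, 10 Monte Carlo iterations;
prototypes are class means and test samples go to the nearest prototype in
Euclidean distance. Both accuracy and mean reciprocal rank are always
reported (MRR is the figure-of-merit for ranked retrieval; accuracy is the
classification rate), with distance ties broken deterministically by
class-id order and counted.

The projection analysis computes, for every ordered class pair $(i, j)$,
the readout $w^{i,j} = (\mu_i - \mu_j)/\lVert \mu_i - \mu_j \rVert_2$,
per-sample projection distances
$p_k = \lvert (x_k^i - \mu_i) \cdot w^{i,j} \rvert$, and the class radius
$R^i = \sqrt{\mathrm{mean}_d \, \mathrm{var}_d(X^i)}$, assembling mean
normalized distances $\hat p^{i,j} = \mu(p^{i,j})/R^i$ into an $M \times M$
matrix with an undefined (missing) diagonal. Summaries average all ordered
off-diagonal pairs; the matrix is deliberately not symmetrized since row
class supplies both samples and radius. The normalization makes the matrix
invariant to uniform rescaling of the features, which is its purpose.
`sphere_projection_demo()` grounds the concentration claim analytically:
projections of uniform unit-ball samples onto a random direction have mean
absolute value $1/2$ at $d = 1$ and $4/(3\pi)$ at $d = 2$, and the mean
decreases in $d$.

## Numerical choices and degenerate inputs

* Sample covariance uses the $n-1$ denominator throughout; ED is
  insensitive to this but the convention is fixed for reproducibility.
* Spectrum estimation always centers; an uncentered mode is not offered.
* All-zero spectra, constant features, single samples, identical centroids,
  zero-radius classes, and missing repeats raise informative errors rather
  than returning NaN.
* Random orthonormal bases fix the sign of the QR diagonal so that a seed
  determines the basis uniquely.
* Seeds: every generator takes one; workflows derive per-stage sub-seeds
  deterministically from a master seed via `derive_seed()` (values kept
  below $2^{31}$).
* Degenerate cloud geometry is allowed: radius 0 collapses classes onto
  centroids (perfect transfer), separation 0 makes classes exchangeable
  (chance transfer); both are exercised in tests.

## Problem sizes

The shipped analyses run at desk scale, chosen to keep every Monte Carlo
estimate comfortably inside its tolerance: spectrum recovery at
$5000 \times 100$; regime sweeps with 20 replicates per grid point
(8-point ED grids, 5-point AP grid); the ED-vs-encoding experiment with 8
grid points $\times$ 5 seeds at 600 stimuli, 100 channels, 50 units; the
transfer grid at the full 50-class protocol; projection matrices at 20
classes $\times$ 30 samples; and $2 \times 10^4$ ball samples per
dimensionality in the concentration demonstration.

## Known limitations

* The measured ED of noisy model features includes the isotropic noise
  floor, so it exceeds the signal spectrum's participation ratio; the
  ED-vs-encoding workflow therefore reports both the analytic target ED and
  the measured ED, and the two are monotonically related under its
  conditions.
* The alignment-pressure construction is one of many bases interpolations
  consistent with a verbal definition of alignment; its guarantees here are
  behavioral (the overlap properties above), not canonical.
* Encoding scores from the simulation are means over ecological dimensions
  of held-out $R^2$ and are not comparable in absolute terms to
  ceiling-normalized neural scores; only orderings are interpreted.
* Nothing in the package estimates the dimensionality of a *brain* from
  data; the analyses characterize models.
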