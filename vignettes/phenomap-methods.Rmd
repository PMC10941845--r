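---
title: "Methods: comparative COPD phenotyping on paired CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative COPD phenotyping on paired CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenomap quantifies chronic obstructive pulmonary disease (COPD) on paired
inspiratory and registered expiratory chest CT through three complementary
lenses — threshold-based parametric response mapping (PRM), density-based
regional anomaly scoring, and latent-space cluster analysis — and compares
their outputs with the statistical toolbox used in quantitative-CT cohort
studies. This vignette explains each model, its assumptions and tunable
parameters, the synthetic cohort that drives testing, and the numerical
choices made where the design was genuinely open.

## Parametric response mapping

PRM classifies every lung voxel jointly by its inspiratory and expiratory
attenuation (Hounsfield units, HU):

| Class  | Inspiratory HU      | Expiratory HU       | Interpretation |
|--------|---------------------|---------------------|----------------|
| Emph   | $[-1000, -950]$     | $[-1000, -856)$     | emphysema      |
| fSAD   | $(-950, -810]$      | $[-1000, -856)$     | functional small-airway disease (non-emphysematous air trapping) |
| Normal | $(-950, -810]$      | $[-856, -500]$      | normal parenchyma |

Voxels outside all three boxes (airways, vessels, very dense or very
aerated tissue) are *Excluded*. The boundary convention is a package
decision because the class intervals share endpoints: $-950$ HU on
inspiration belongs to Emph and $-856$ HU on expiration belongs to Normal.
Under this closure the three boxes are pairwise disjoint, so every lung
voxel receives exactly one label; the tests assert this partition property
and the boundary behaviour explicitly.

Relative class volumes are reported against the PRM-classified voxels
(the three percentages sum to 100), while the Excluded share is reported
separately against all lung voxels. The classical one-threshold measures
LAA-950 (inspiration) and LAA-856 (expiration) are computed alongside.

## Patch extraction and featurization

The anomaly and clustering branches operate on overlapping cubic patches
of side 50 voxels with 20% overlap, i.e. stride
$\mathrm{round}(50 \times 0.8) = 40$, with the final tile clamped to end
at the volume edge. Axes shorter than the patch (the default synthetic
grid has 48 axial slices) shrink the patch extent on that axis. Patches
whose lung content falls below `min_lung_fraction` are dropped.

`min_lung_fraction` defaults to 0.2. With the default synthetic geometry
(two ellipsoidal lungs filling roughly a third of a 64×64×48 grid), kept
patches carry lung fractions around 0.45 and the union of kept patches
covers the entire lung; a threshold of 0.5 would discard every patch on
these grids. The tests assert the >70% lung-coverage property on default
masks.

Each patch pair is mapped to one fixed-length vector. The default
featurizer is a deterministic histogram summary: lung-voxel HU densities
over 32 bins per phase on $[-1024, 0]$ HU, the per-phase mean and SD, and
the patch-level LAA-950/LAA-856 fractions, zero-padded to dimension `d`
(512 by default, mirroring the dimensionality such latent vectors
typically have; the padding is inert under the PCA steps downstream). A
lightweight contrastive encoder is available as an alternative
featurizer: a linear map on pooled patch intensities trained with an
InfoNCE objective over augmented views (axis flips, random crop-resize,
HU jitter), with analytic gradients and full seed determinism. It is a
desk-scale stand-in exposing the same interface as a learned 3D encoder,
and makes no claim of equivalence to one; the tests check its
optimization behaviour (loss decrease, augmented views more similar than
random pairs), not representational quality.

## Anomaly scoring

The normative reference is the set of patches with less than 1%
emphysema (patch-level LAA-950 on inspiration — the package's
operationalization, since region-level emphysema measurement is
otherwise unspecified) from subjects without airflow obstruction
(never-smoker controls and GOLD 0). A reference density is fitted to
those patches' features:

* optional PCA-whitening to at most `whiten_dims` dimensions (default 16
  in the pipeline, 32 in the function) keeps covariance estimation
  well-posed at small reference sizes; the transform is stored with the
  density;
* the density itself is a full-covariance Gaussian mixture whose
  component count is chosen by minimum BIC over `k_range` (default 1–8),
  with a $10^{-6}$ ridge on every covariance; a single Gaussian is
  available for tiny reference sets.

Each patch is scored by its negative log-likelihood (NLL, nats) under
the reference — larger means more anomalous — and patient scores
aggregate patch scores by the mean (median and max are selectable and
recorded). For map rendering, each lung voxel receives the mean score of
all patches containing it, normalized by the 5th and 95th percentiles of
the analysis cohort's patch-score distribution and clipped to $[0, 1]$.
Degenerate normalization (p95 = p5) yields an all-zero map with a
warning rather than an error.

## Latent structure

PCA is computed on mean-centered (not variance-scaled) features.
Component retention is decided on the correlation-scale eigenvalue
spectrum, where Horn's parallel analysis and the Kaiser criterion are
both well defined regardless of feature scaling: Horn keeps components
whose eigenvalue exceeds the 95th percentile of position-matched
eigenvalues from 100 same-shape standard-normal surrogate matrices
(counted contiguously from the top); Kaiser counts eigenvalues above 1
and is reported alongside. Retention follows Horn.

Clustering compares mini-batch k-means (k-means++ seeding, batch size
1000, per-center learning rates — at the suite's problem sizes the
batches are full, so it converges to the ordinary Lloyd fixed point) and
full-covariance Gaussian mixtures over `k_range` (default 2–8). Every
candidate is scored by Silhouette (maximized), Davies–Bouldin
(minimized) and Calinski–Harabasz (maximized); the selected model
minimizes the mean rank across the three metrics, with ties broken
toward smaller k. Calinski–Harabasz is treated as higher-is-better, its
standard orientation, even though some texts describe it otherwise.
Degenerate fits (an empty cluster) are retried with fresh seeds before
erroring. Per-subject cluster volumes are the fractions of a subject's
patches per cluster (summing to one), and cluster maps paint each lung
voxel with the label of the nearest patch center (ties toward the lowest
label).

t-SNE is provided strictly for visualization: an exact $O(n^2)$
implementation (perplexity 30, PCA initialization, early exaggeration)
fitted on an evaluation set, with new points placed at the
similarity-weighted mean of their nearest fitted neighbours. No
quantitative claims rest on the embedding beyond a class-separation
check.

## Cohort statistics

* **Jonckheere–Terpstra** trend test over ordered severity stages:
  concordant cross-group pairs with ties counted one half, tie-corrected
  null variance, and a continuity-corrected normal approximation
  (verified against a 100,000-permutation null within 0.01); an explicit
  Monte-Carlo permutation p is available for small samples.
* **Tukey HSD** post-hoc pairwise stage contrasts via the studentized
  range.
* **Pearson correlations** with 10,000-resample percentile bootstrap
  intervals and interpretive bands (0.10/0.40/0.70/0.90 cutpoints).
* **Zou's method** for the difference of two dependent overlapping
  correlations (two imaging measures against one shared clinical
  variable), assembled from Fisher-z interval endpoints and the
  estimated co-dependence through the correlation of the non-shared
  measures; the null of equal correlations is rejected when the 95% CI
  excludes zero.
* **Holm–Bonferroni** step-down adjustment wherever families of tests
  are reported.
* **Linear mixed models** with a random study-site intercept, fitted by
  maximum likelihood so nested models are comparable by likelihood-ratio
  test. Reported fit quality is the Nakagawa–Schielzeth conditional
  $R^2$ — (fixed + random variance) / total — with an Ezekiel-style
  adjustment $1-(1-R^2)(n-1)/(n-p-1)$ for the number of fixed
  regressors; the adjustment is isolated in one function so it can be
  swapped. The anomaly score enters standardized so all fixed effects
  share comparable scales.
* **Regression-based Bland–Altman**: when the difference between two
  methods drifts with their average (even after log transform), bias is
  modelled as $D = a + bA$ by OLS and the 95% limits of agreement follow
  the fitted line at $\pm 1.96\,\mathrm{SD}$ of the residuals
  (constant-width band, matching the usual printed form); a
  variable-width band from a regression of absolute residuals is also
  reported. On the log scale, pairs with nonpositive values are excluded
  and counted rather than offset.

## The synthetic cohort

Real paired-CT cohorts are not redistributable, so every stage is
exercised against a generator with voxel-level ground truth. Per
subject:

* the lung is two ellipsoids inside the grid (default 64×64×48 at
  2.5 mm isotropic, about 70k lung voxels);
* emphysema and fSAD burdens are Beta draws around per-stage means
  calibrated to published per-GOLD-class PRM volumes (emphysema
  0.3/0.9/2.6/6.8/13.3/29.5%, fSAD 7.1/14.7/22.0/28.9/39.4/45.1% for
  controls through GOLD 4), with concentration 30. For small means the
  effective concentration is floored at $1/m$ so the Beta's first shape
  parameter never drops below 1: below that floor the distribution
  degenerates into a spike at zero with a heavy tail, occasionally
  producing "controls" with more emphysema than a GOLD 2 class mean,
  which contradicts the narrow dispersion such healthy classes show
  (0.3±0.3%). For controls the floored rule reproduces that printed
  dispersion almost exactly.
* lesions are spherical blobs (radius 2–5 voxels) placed at random lung
  centers until the drawn burden is met exactly (the last blob is
  trimmed at random);
* HU values are truncated normals per tissue class, placed inside the
  PRM box each class is designed to hit (e.g. emphysema inspiration
  $N(-975, 12)$ on $(-1000, -950)$); truncation guarantees PRM recall of
  the ground truth by construction, which is what makes recall a
  meaningful end-to-end bookkeeping check rather than a statistical
  claim;
* clinical variables are linear in the two burden fractions plus a
  per-site random intercept and Gaussian noise, clipped to physiological
  ranges, with signs following the known clinical correlates (spirometry
  and walk distance fall with burden; gas volumes, BODE and SGRQ rise)
  and intercepts consistent with published class summaries — e.g.
  $\mathrm{FEV1\%pred} = 98 - 160\,e - 70\,f + \mathrm{site} + N(0,8)$.
  Controls are never-smokers with zero smoking duration.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: CT noise texture and reconstruction
kernels, airway and vessel trees (so the Excluded class is nearly empty
here), registration error between inspiration and expiration (volumes
are emitted pre-registered by construction), scanner/protocol
variability beyond a site intercept, and any nonlinear
burden–physiology relationships.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to give the
statistical checks adequate power while staying desk-scale: 30 subjects
per stage for calibration/recall checks, 20 per stage for the anomaly
and mixed-model checks, 10 per stage for the end-to-end determinism run,
$10^6$ random HU pairs for the classifier-equivalence check, 100 seeds
for Horn-recovery rates, and 200 replicates for size/coverage
simulations. Other numerical choices: covariance ridge $10^{-6}$;
whitening components capped and pruned at a relative SD of $10^{-8}$;
k-means++ initialization with up to 3 seed retries on degenerate
clusters; silhouette/DB/CH evaluated on a capped subsample (2000) for
large inputs; all randomness flows through explicit seeds with
per-subject substreams derived from the master seed, and library RNG use
is isolated so user RNG state is never clobbered.

## Known limitations

The histogram featurizer ignores spatial texture within a patch; the
contrastive encoder is linear and trained at toy scale; the t-SNE
transform is an interpolation, not the full out-of-sample optimization;
mixture BIC selection can be unstable for reference sets barely larger
than the whitened dimension (a single Gaussian is the robust fallback);
and the generator's linear clinical model makes mixed-model recovery
easier than it would be on real cohorts, where the same pipeline should
be interpreted as a comparison framework rather than a validated
clinical predictor.
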