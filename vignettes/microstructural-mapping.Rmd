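---
title: "Data-driven microstructural mapping of subcortical structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven microstructural mapping of subcortical structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtexmap)
```

## The problem

Subcortical gray-matter structures such as the amygdala are internally
heterogeneous: cytoarchitecture and myeloarchitecture vary smoothly across
them, and classical subdivisions (for the amygdala, the centromedial,
laterobasal and superficial groups) are coarse summaries of that variation.
`subtexmap` maps this internal organization directly from a volumetric
intensity image — ultra-high-resolution histology or quantitative MRI — and
a binary mask of the structure, without requiring a manual parcellation. The
pipeline has five stages:

1. **Texture feature bank.** For every masked voxel and every kernel radius
   $r$, the first four central moments (mean, variance, skewness
   $m_3/m_2^{3/2}$, raw kurtosis $m_4/m_2^2$) of the masked intensities in
   the cubic window of edge $2r+1$, after excluding values deviating more
   than `outlier_sd` (default 1) SD from the window mean. Four moments at
   five radii give a 20-column voxels-by-features matrix, z-scored per
   column.
2. **Voxel embedding.** UMAP (neighborhood size 15, minimum distance 0.1,
   its standard settings) projects the normalized bank to two components U1
   and U2. Rotation and signs are fixed by an orientation convention
   (`orient_embedding()`), since embedding coordinates are only defined up
   to rotation and sign.
3. **Spatial-axis statistics.** Pearson correlations between each component
   and the three anatomical axis coordinates, with significance from
   variogram-matched surrogate maps — nulls that preserve the map's spatial
   autocorrelation while destroying its alignment with the axes.
4. **Atlas validation.** Against a probabilistic subregion atlas: per-region
   top-5% cores, a maximum-probability parcellation, and a one-way ANOVA of
   component values across subregions whose null distribution again comes
   from the spatial surrogates.
5. **Functional contrast.** Per subject, the top and bottom quantile
   (default 25%) of U1 define two seed subregions; their Fisher-z
   seed-to-cortex connectivity profiles are contrasted across subjects with
   a paired test and max-statistic sign-flip permutation FWE control, then
   stratified by functional network and decoded against term maps.

Every stage is exercised against synthetic volumes with planted ground truth
(`make_gradient_volume()`, `make_tiled_atlas()`,
`make_coupled_timeseries()`), so the package's claims about itself are
checked by construction rather than by eye.

## Windowed robust moments

The moment estimators are population (denominator $n$) forms, the standard
first-order radiomics definitions; kurtosis is reported raw (normal
$\approx 3$), not excess. Outlier exclusion uses the *window's own* mean and
population SD as the reference: exclusion happens independently inside every
kernel, which is the reading consistent with exclusion being applied "at
each kernel size"; a `global_reference = TRUE` flag switches to a
volume-wide reference for sensitivity analyses. The exclusion pass runs
once — survivors are not re-screened. Degenerate windows (fewer than two
survivors, or zero variance) yield variance/skewness/kurtosis 0 rather than
NaN, keeping the bank dense for the embedding; and if a sub-1-SD threshold
ever excludes everything, the value closest to the reference mean is kept.
Kernels are cubes of edge $2r+1$ clipped at the grid border (a spherical
option exists but is not the default): at 100 µm voxels, radii 2–10 in steps
of 2 give physical windows of 500–2100 µm; at 500 µm voxels, radii 1–5 give
1500–5500 µm. Only masked voxels ever enter a window, so tissue outside the
structure cannot leak into its features.

## The embedding harness

The nonlinear reducer itself (UMAP, via `uwot`) is used as an external
numerical primitive at its standard settings; what the package adds is the
determinism harness around it: a fixed seed, single-threaded optimization,
the stable voxel ordering shared by all stages, and an orientation
convention. The reducer's output is only defined up to a rotation of the
(U1, U2) plane and a sign per component — the optimizer can emit the same
layout rotated arbitrarily, and on synthetic volumes roughly one run in six
lands ~45° off, halving per-component axis correlations even though the
recovered geometry is identical. `orient_embedding(rotate = TRUE)`, used
throughout the pipeline, therefore first rotates the centred coordinate
cloud to its own principal axes (intrinsic, deterministic, pairwise
distances untouched) and then flips each component so it correlates
non-negatively with a chosen reference axis. With `rotate = FALSE` the raw
reducer axes are kept and only signs are fixed. All downstream statistics
(|r|, surrogate p-values, F) are invariant to sign, and rigid rotation
changes no distance-based quantity.
Masks larger than `budget` voxels (default 50&nbsp;000) are embedded via a
uniform subsample plus out-of-sample projection; typical structure masks are
far below this.

## Variogram-matched spatial nulls

Voxelwise maps of a compact structure are strongly autocorrelated, so
correlating a component with a smooth axis coordinate and reading
significance off a permutation null is badly anticonservative — in the
package's own calibration experiment, plain permutation nulls reject a true
null more than 80% of the time at $\alpha = 0.05$. The surrogate generator
follows the variogram-matching idea of Viladomat et al. (2014): each
surrogate permutes the map, smooths the permutation with a k-nearest-
neighbor kernel (Gaussian decay $e^{-(d/d_k)^2}$ truncated at the k-th
neighbor; exponential decay available via `kernel = "exp"`) at
each of a set of candidate scales, linearly rescales (slope and nugget
offset, realized as added white noise) to best match the empirical
variogram, keeps the best-fitting scale, and finally rank-maps the result
onto the original value set so the marginal distribution is preserved
exactly. The empirical p-value uses the plus-one rule,
$(1 + \#\{|r_\mathrm{null}| \ge |r_\mathrm{obs}|\})/(S+1)$, and so is never
exactly zero.

Numerical choices, and why:

* **Candidate scales** default to fractions
  {0.005, 0.01, 0.02, 0.05, 0.1, …, 0.9} of the voxel count. The grid must
  bracket the map's true correlation length; for desk-scale masks of a few
  thousand voxels, a 0.1 fraction already implies a kernel radius of several
  voxels, so purely coarse grids over-smooth every surrogate and make the
  test over-conservative. The added fine fractions let the fit choose
  kernels at or below the map's own smoothness.
* **Kernel shape**: Gaussian decay by default. In calibration experiments
  the exponential kernel's heavier tail gave surrogates slightly too much
  long-range power, pushing the type-I rate of the axis test to ~0.01–0.015
  instead of the 0.02–0.05 the Gaussian kernel achieves on smooth fields.
* **Variogram binning**: 25 equal-width distance bins up to half the
  maximum pair distance. The deterministic upper bound for distances is the
  masked bounding-box diagonal.
* **Pair budgets**: `empirical_variogram()` reports with up to $10^5$
  sampled pairs; the per-surrogate fit inside `variogram_surrogates()` uses
  $10^4$ — the fit needs only a coarse variogram, and the larger budget
  would multiply runtime roughly tenfold with no measurable effect on the
  chosen scales.
* **Precomputation**: `surrogate_model()` builds the pairwise distance
  matrix, per-scale truncation radii and (when they fit in memory) the dense
  smoothing kernels once per voxel table; ensembles for any number of maps
  on the same table reuse it. Smoothing is a dense matrix product, so the
  heavy work runs in BLAS.
* **Ensemble size**: 1000 by default (resolving p-values to $10^{-3}$);
  tests and the calibration experiment use 500, and anything down to ~100
  still resolves $p < 0.05$.

The package's calibration check (in the test suite) generates 200 smooth
Gaussian random fields on a ~3000-voxel mask with no axis dependence and
requires the rejection rate at $\alpha=0.05$ to fall in [0.02, 0.10], while
the naive permutation test on the same fields must show its characteristic
inflation (> 0.15). Matched nulls condition on the observed map's own
autocorrelation, so mild conservatism is expected; rates far below nominal
would indicate surrogates with excess long-range structure.

## Atlas validation

"Highest 5% probability values" is implemented as the count-based top
$\lceil 0.05\,n\rceil$ voxels per region (ties broken by voxel index, so the
operation is deterministic), giving conservative subregion cores; a
probability-value cut can be emulated by thresholding the map beforehand.
Voxels retained by several regions go to the retaining region of highest
probability, ties to the lowest region index (logged). The F statistic for
component differences across subregions is the textbook one-way form; its
null recomputes F on each variogram-matched surrogate with labels held
fixed, because voxelwise autocorrelation makes the nominal F distribution
meaningless here — thousands of non-independent voxels would otherwise
inflate both degrees of freedom and F. A plain permutation null is available
by passing a `permutation_surrogates()` ensemble instead.

## Functional contrast

With both seeds observed in every subject, the estimable core of a
subject-random-intercept model at small n is the paired high-minus-low
contrast: per vertex, a one-sample t on the per-subject difference of
Fisher-z profiles, with nuisance covariates (age, sex) residualized out of
the differences first (covariates are centered; the tested intercept is
untouched). Family-wise error is controlled by max-statistic sign-flip
permutation: whole subjects' difference maps flip sign together, the maximum
|t| over vertices is recorded, and each vertex's $p_\mathrm{FWE}$ is the
plus-one proportion of permutation maxima reaching its observed |t|. This
replaces random-field-theory cluster correction deliberately: it is exact
under exchangeability, assumption-light, works on abstract vertex sets (the
package treats cortical geometry as a plain vertices-by-time matrix plus a
network label vector), and is directly testable. Correlations are clamped to
$\pm(1-10^{-7})$ before the z-transform so all values stay finite;
zero-variance series yield z = 0 with a warning rather than NaN.

## What the synthetic data emulate — and what they do not

`make_gradient_volume()` plants two independent ground-truth axes: the local
mean rises linearly along one anatomical axis (default slope 0.3 intensity
units/voxel), and the local skewness runs linearly from −0.9 to +0.9 along a
second axis, realized by inverting the skew-normal skewness formula for its
shape parameter (the skew-normal caps marginal skewness just below 1; using
one shape parameter makes skewness and kurtosis co-vary, as they do in real
texture). The default effect sizes were fixed once, during generator design,
so that windows are texture-dominated: with texture SD 2 and additive noise
SD 0.5, the mean drift across even the largest default window (21 voxels ×
0.3 ≈ 6 units across the window, ~1.5 units within a half-window) stays
comparable to the texture SD, so higher-moment features measure the planted
asymmetry rather than within-window mean drift — the regime in which
windowed moments are meaningful descriptors at all. The default mask is a
~7800-voxel ellipsoid in a 40³ grid: large enough for stable variograms and
embeddings, small enough that the full pipeline runs in seconds to minutes
on one core (tests use masks from ~700 to ~7800 voxels depending on how many
replicates a property needs).

`make_coupled_timeseries()` generates network latents, cortical vertices
loading on their own network's latent (0.7), and structure voxels loading on
the designated network's latent with a weight that rises with the voxel's
component value (`effect` spans the weight range). Every voxel also carries
a shared structure-internal latent (0.6) independent of all cortical
networks. That term is essential, not decorative: averaging hundreds of
voxels into a seed cancels independent voxel noise, and without a shared
background both quantile seeds would collapse onto the designated network's
latent and the planted contrast would vanish — in real data, regional
fluctuations are likewise shared across neighboring voxels.

What the generators do *not* emulate: staining or relaxometry intensity
statistics of real tissue, anisotropic voxels, oblique acquisition grids,
mask-boundary segmentation error, physiological noise spectra, or
inter-subject anatomical variability (all synthetic subjects share one mask
and component map). Passing tests therefore show that the pipeline recovers
the kinds of structure it assumes — monotone moment gradients, axis-tiled
subregions, component-graded coupling — at realistic sizes and noise
levels; they do not certify performance on any particular real dataset.

## Degenerate inputs and tie-breaking

* Masks must contain at least one voxel; volumes must be 3D and grid-aligned
  (oblique affines are rejected with an error rather than silently
  approximated — axis correlations are only meaningful on axis-aligned
  grids).
* Written scalar maps use NaN, not 0, as background.
* All top-k selections (`threshold_top_fraction()`,
  `quantile_subregions()`) break ties by ascending voxel index; quantile
  masks whose rounded sizes would overlap (e.g. fraction 0.5 with odd n)
  are an error rather than an arbitrary split.
* Zero-variance feature columns normalize to all-zero with a warning;
  normalizing twice is an error.
* Constant value sets have variance/skewness/kurtosis 0 by convention.

## Known limitations

* Exact embedding coordinates depend on the reducer's implementation and
  seed; only seeded determinism on one platform is guaranteed, and no
  attempt is made to reproduce any particular published U1/U2 numerically.
  Axis correlations, surrogate p-values and subregion F statistics are the
  stable, comparable surface.
* Variogram-matched nulls are mildly conservative by construction (they
  condition on the observed map's realized autocorrelation).
* The paired contrast is an approximation to a full mixed-effects model; it
  is exact for the balanced two-seeds-per-subject design the pipeline
  produces, but does not generalize to missing seeds or unbalanced designs.
* The functional stage consumes preprocessed time series as given; no
  motion, distortion or denoising steps are provided, and no registration
  between image spaces is performed anywhere in the package.

## A worked miniature

```{r mini, eval = FALSE}
mask <- make_ellipsoid_mask()   # the default ~7800-voxel ellipsoid
vol  <- make_gradient_volume(mask, gradient_spec(seed = 1))
tab  <- voxel_table(vol)
bank <- normalize_bank(build_feature_bank(vol))
emb  <- orient_embedding(embed_bank(bank, embedding_config(seed = 1)), tab,
                         rotate = TRUE)

ens <- variogram_surrogates(emb$coords[, "U1"], tab,
                            n_surrogates = 500, seed = 2)
axis_correlation_test(emb$coords[, "U1"], tab, "inferior-superior", ens)

atlas  <- make_tiled_atlas(mask)
cores  <- lapply(1:3, function(g) threshold_top_fraction(atlas$prob[, g], 0.05))
labels <- maximum_probability_map(atlas, cores)
anova_with_surrogate_null(emb$coords[, "U1"], labels, ens)
```

The `scripts/acceptance.R` script at the repository root runs this pipeline
end to end at the default synthetic scale and writes the resulting
quantities (axis correlations, surrogate p-values, subregion F statistics,
contrast sensitivity and FWE rates) to JSON.
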