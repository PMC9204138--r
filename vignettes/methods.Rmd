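---
title: "Predicting cell counts from diffusion MRI metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell counts from diffusion MRI metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwicell)
```

## The problem

Diffusion-weighted MRI is sensitive to tissue microstructure, but the
mapping from its scalar metrics to explicit cytoarchitectural quantities —
how many cells, of which class, sit in a voxel — is poorly characterized,
especially in gray matter. `dwicell` implements an analysis framework for
that question at the scale of a small animal cohort: relate six voxel-wise
diffusion metrics (the tensor scalars AD, ADC, FA, RD and the NODDI scalars
NDI, ODI) to per-voxel counts of six cell classes (all cells, neurons, all
glia, oligodendrocytes, astrocytes, microglia), and then try to predict the
counts from the metrics alone, one brain region at a time.

Because real multi-shell ex vivo acquisitions with matched histology are
not available at desk scale, the package treats the *synthetic phantom
cohort generator* as a first-class module: it produces cohorts with exactly
the statistical structure the analysis machinery assumes, so every stage
can be validated against known ground truth.

## The phantom generator

`makeCohort()` draws, per cohort:

1. **Reference count fields.** For each base cell class (neurons,
   oligodendrocytes, astrocytes, microglia) a smooth nonnegative field:
   region-specific baseline density plus a Gaussian random field smoothed
   with `countFieldSigma` (default 3 voxels) and scaled by a per-class
   amplitude, clipped at zero. Aggregates are formed by summation, so the
   hierarchy *Cells = Neurons + Glia* and *Glia = Oligodendrocytes +
   Astrocytes + Microglia* holds exactly by construction. Counts are
   real-valued densities (cells per voxel), not integers, because the
   analysis always works with per-voxel and per-block averages. Default
   baselines (e.g. 200 neurons/voxel at 0.125 mm isotropic) correspond to
   plausible rodent gray-matter densities of order 10^5 neurons/mm^3.
2. **Subject misalignment.** Each subject's count fields are the reference
   fields sampled through a smooth random displacement field of magnitude
   `jitterSd` (default 0.5 voxels, smoothness 4 voxels). This emulates
   residual registration error — precisely the nuisance the block
   regridding step is designed to absorb. The reference counts stay
   jitter-free: they play the role of the shared cell-count atlas.
3. **Metrics.** Within each region, each metric is an affine function of
   designated count fields plus i.i.d. Gaussian noise, e.g. FA increasing
   with glia density in one region and decreasing in another. Slopes are
   calibration choices (nothing quantitative is published about per-region
   effect sizes); the defaults scale the count-driven metric variation to a
   few times the noise sd (noise defaults: 0.02-0.04 in metric units).
   `defaultRelationships()` anchors each metric at its typical value
   (e.g. FA 0.35) at baseline counts, so regions with opposite slope signs
   still have overlapping metric distributions — region identity must not
   be readable from the metric level alone. FA, NDI and ODI are clipped to
   [0, 1] (a no-op under the default dynamic ranges). A monotone
   nonlinearity hook was considered and omitted: the affine form plus the
   tree-ensemble learner already covers the qualitative behaviours the
   validation needs.

Everything is a pure function of the spec's master seed via named
substreams (`seedFrom()`), which is what makes whole-pipeline byte-level
reproducibility testable.

What the phantoms deliberately do *not* emulate: partial-volume mixing at
region borders, spatially correlated (non-i.i.d.) metric noise, scanner
drift, inter-subject differences in the true counts, or any biophysical
NODDI signal model (NDI/ODI are generated as abstract fields). Passing
tests therefore show that the *machinery* is correct and well-calibrated
under its own assumptions, not that real tissue obeys them.

## DWI simulation and the tensor fit

`simulateDWI()` implements the monoexponential tensor forward model
$S = S_0 \exp(-b\, g^{\mathsf T} D g)$ per scheme entry, with optional
Rician noise (magnitude of a complex Gaussian perturbation). The default
scheme mirrors a two-shell ex vivo protocol: 2 b=0 volumes, 20 directions
at b = 1,000 s/mm^2 and 52 at b = 3,000 s/mm^2, with direction tables
built by antipodally-symmetric electrostatic repulsion (no published
direction table exists to copy). b-values are converted to ms/um^2
internally so diffusivities are in um^2/ms; conversion happens only at the
I/O boundary.

`fitTensorWLS()` solves the log-linear tensor design by weighted least
squares with weights equal to squared observed signals, then repeats once
(default) with weights from the predicted signals — the iterated-WLS
scheme standard in tensor toolkits. Numerical choices:

* Nonpositive signals are clipped to `1e-6` of the voxel's mean b0 signal
  before the log; the log-domain fit requires positivity.
* Negative fitted eigenvalues are *retained* for scalar computation but
  flagged in a QC mask; clamping them would silently bias FA. Only at
  flagged voxels is FA capped into [0, 1].
* FA of the zero tensor is defined as 0.

## Regridding and block-size selection

Region masks are eroded by 3 one-voxel passes of 6-connected morphological
erosion ("eroded by a factor of 3" read as 3 iterations; connectivity and
count configurable) to guard against partial-volume effects at region
borders. The grid is then tiled from array index (1,1,1) into cubic blocks
of edge `factor`; per block, every metric and count volume is averaged
over the in-mask voxels. Blocks with less than `minFill = 0.5` of a full
cube in-mask are dropped — boundary handling is unspecified in the
literature, and 50% keeps block means comparable without discarding most
of a small region. Tiling phase is fixed at the array origin; voxel
bookkeeping is integer, physical mm only at I/O.

The block edge is chosen by `optimizeBlockFactor()`: for each candidate,
compute the variance of each metric across subjects within each block,
take the median over blocks (block counts differ between factors), average
over the six metrics, and pick the factor minimizing this inter-subject
variance; ties break toward the smaller factor (more spatial resolution at
equal cost). Variance uses denominator n−1; the convention is fixed so
hand-computed oracle values are stable. The criterion is evaluated on the
whole eroded all-region mask by default (configurable per region).

## Correlation statistics

Per subject, Pearson correlations between each metric and each count over
blocks; per (metric, cell type) pair, the subject correlations are Fisher
Z transformed (`atanh`, with |r| = 1 clipped to 1 − 1e-12 so noiseless
phantoms stay finite) and tested against zero with a one-sample t-test
(df = n−1, two-sided — signed t-values are the reported quantity). The 36
raw p-values of one region's matrix form the Holm-Sidak correction family;
a global family across regions is possible by calling `holmSidak()` on
pooled p-values, but the per-matrix family is the default since each
region's matrix is interpreted on its own. Pairs undefined in some
subjects (constant columns) are tested on the remaining subjects when at
least two remain, otherwise reported NA and excluded from the family.

Blocks are treated as independent observations in both the correlation
p-values and the prediction p-values (df = blocks − 2). They are not truly
independent — neighbouring blocks share smooth field structure — and no
spatial autocorrelation correction is applied; this mirrors the practice
the framework is built around and is a stated limitation.

## Prediction pipeline

The six metrics are strongly collinear, so block features are first
compressed by a small fully-connected autoencoder (`fitCompressor()`):
linear encoder/decoder by default (latent dimension 3 of 6), optional tanh
hidden layers, trained full-batch by Adam on mean squared reconstruction
error. Features are standardized with training-fold statistics only; the
compressor stores them, so nothing leaks from test folds. A linear
autoencoder's optimum spans the leading principal subspace, which is the
right amount of machinery for collinearity removal at a few hundred
training rows; the architecture, epochs (300) and learning rate (0.02)
are exposed in `compressorConfig()` and logged with every result.

The regressor is an extremely-randomized-trees ensemble (randomized split
thresholds, trees grown on bootstrap resamples; `ranger` backend with
`splitrule = "extratrees"`). Hyperparameters are chosen by 5-fold
cross-validated grid search scored on mean out-of-fold Pearson R — the
framework optimizes *relative*, not absolute, predictive power. The
default grid crosses trees {250, 1000}, split candidates {1, all} and
minimum leaf {1, 5}; exact ties resolve to the simpler model (fewer trees,
larger leaf, fewer candidates) by grid ordering.

Evaluation designs:

* **Leave-one-subject-out** (`looEvaluate()`): one whole subject per fold;
  each block's final prediction is the mean over folds; Pearson R, its
  t-transform p, and the predicted-vs-reference line are computed on the
  averaged predictions. A structural leakage guard asserts train/test row
  disjointness on every fold.
* **Bootstrap distributions** (`bootstrapPerformance()`): parameters fixed
  once per region by the usual grid search, then per iteration the
  training and testing rows of every fold are independently subsampled
  without replacement (default 80%, 1,000 iterations; 70% for the
  subsampling robustness check) and R/p/slope recorded. Iterations leaving
  fewer than 3 predicted blocks are redrawn.
* **Transfer** (`transferEvaluate()`): fit on one region or hemisphere,
  evaluate on a disjoint one; overlapping block sets are a hard error.

The ensemble's internal bagging is the "bootstrapped subsamples" of the
training step; the 80%/1,000 performance loop is a separate outer
mechanism. Both are configurable independently.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run everything on phantoms of
roughly 56 x 30 x 30 voxels with two ~26^3 regions, block factor 4 (~120
blocks per region), a singleton tree grid of 100 trees and 150 autoencoder
epochs. These sizes were chosen so a full validation sweep (including 20
null-phantom LOO runs and a 1,000-iteration family-wise-error simulation)
completes in minutes on one CPU while leaving every statistical
conclusion comfortably away from its threshold; the package defaults
(10-50 voxel factor search range, 250/1000-tree grids, 1,000 bootstrap
iterations) are the ones intended for real-scale data.

## Known limitations

* The pooled-versus-regional contrast depends on the phantom construction:
  because all subjects share one reference count field, a pooled model can
  partially memorize block identity from the 6-D feature vector (the
  "lookup table" failure mode) and so scores above chance even when the
  metric-to-count mapping is not invertible across regions; it still
  scores consistently below the region-specific models, which is the
  qualitative claim under test.
* Counts are predicted in relative terms; no absolute-count calibration is
  attempted.
* NDI/ODI are abstract fields here; no multi-compartment biophysical model
  is fitted.
* p-values ignore residual spatial dependence between blocks (see above).
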