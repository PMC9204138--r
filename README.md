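# dwicell

Region-specific prediction of brain cell counts from diffusion MRI
microstructure metrics.

## What this is for

Diffusion-weighted MRI metrics — the tensor scalars AD, ADC (mean
diffusivity), FA and RD, and the NODDI scalars NDI and ODI — are sensitive
to gray-matter microstructure, but what cytoarchitecture they reflect is
poorly characterized. `dwicell` implements an analysis framework for small
animal cohorts that (a) quantifies, per brain region, how each diffusion
metric correlates with per-voxel counts of six cell classes (Cells,
Neurons, Glia, Oligodendrocytes, Astrocytes, Microglia), and (b) predicts
those counts from the metric "signature" of each voxel block with a
tree-ensemble model — one model per region, because the metric/count
relationships differ between regions and can even flip sign.

The statistical core, applied to block-averaged data on a common grid:

* per-subject Pearson correlation of every metric x cell-class pair, with
  the group result summarized as the one-sample t statistic of the Fisher
  Z scores, `t = mean(z) / (sd(z)/sqrt(n))`, Holm-Sidak corrected over the
  36 pairs of a region's matrix;
* cubic block regridding of eroded region masks, with the block edge
  selected by minimizing inter-subject variance (median over blocks, mean
  over metrics);
* an extremely-randomized-trees regressor on autoencoder-compressed
  metrics, tuned by Pearson-R-scored 5-fold grid search, evaluated by
  leave-one-subject-out cross-validation and 80%/1,000-iteration
  subsampling distributions, with hemisphere/region transfer checks;
* a weighted-least-squares diffusion tensor fit (one iterated reweighting
  pass) and a two-shell DWI signal simulator for exercising it;
* a synthetic phantom-cohort generator that produces multi-subject
  cohorts with known region-specific metric/count relationships, subject
  misalignment jitter and configurable noise — the ground truth against
  which everything above is validated.

## Worked example

```r
library(dwicell)

atlas <- makeAtlas(c(56, 30, 30), list(
  CA1 = cuboidRegion(c(2, 4, 4), c(27, 27, 27)),
  CTX = cuboidRegion(c(30, 4, 4), c(55, 27, 27))))
cohort <- makeCohort(atlas, cohortSpec(atlas, seed = 7L))

regionCorrelationMatrix(cohort, "CA1", factor = 4)
#> CorrelationMatrix for region CA1 (n = 6 subjects, factor = 4, alpha = 0.05)
#>       Cells Neurons    Glia Oligodendrocytes Astrocytes Microglia
#> AD   -86.39  -44.21 -196.01           -87.39       8.57     -7.04
#> ADC  -74.59 -120.62  -63.62           -62.74     -20.19    -34.98
#> FA    71.56   22.96  126.71            64.98      38.06     90.74
#> RD  -133.68  -88.77  -80.27           -85.29     -17.43    -44.49
#> NDI  130.21  112.58   24.40            32.72     -15.50     31.68
#> ODI   46.59   24.09   76.86             7.79      9.18     121.98
#> 36 of 36 pairs significant after Holm-Sidak

looEvaluate(cohort, "CA1", "Glia", factor = 4,
            grid = data.frame(num.trees = 250, mtry = 2, min.node.size = 5))
#> PredictionResult: Glia in CA1
#>   120 blocks; R = 0.968 (p = 2.46e-72), fit: pred = 0.849 * ref + 16.398
```

The t-matrix shows each metric/count pair's group-level evidence: e.g. FA
correlates positively with glia in this phantom region (by construction),
and the sign pattern flips in the second region. The prediction result
says that, across the region's 120 blocks, counts predicted from metrics
alone track the reference glia counts with Pearson R = 0.97; the slope
below 1 reflects the usual shrinkage of relative (not absolute) count
prediction.

End-to-end runs with provenance come from a YAML config:

```r
runPipeline(system.file("extdata", "demo_config.yaml", package = "dwicell"))
```

or the CLI wrapper `inst/scripts/dwicell-pipeline.R --config <yaml>`.

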