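#' @import methods
NULL

#' DWI gradient scheme
#'
#' Holds the b-value and unit gradient direction of every volume of a
#' diffusion-weighted acquisition, one entry per volume. b-values are stored
#' in s/mm^2 (the convention of FSL-style bval files); internal tensor
#' computations convert to ms/um^2 so diffusivities come out in um^2/ms.
#'
#' @slot bvals numeric vector of b-values (s/mm^2).
#' @slot bvecs 3 x n numeric matrix of gradient directions; columns for
#'   b > 0 entries must have unit norm (tolerance 1e-6), b = 0 columns are
#'   arbitrary.
#' @export
setClass("GradientScheme",
  slots = c(bvals = "numeric", bvecs = "matrix"))

setValidity("GradientScheme", function(object) {
  msgs <- character()
  if (nrow(object@bvecs) != 3L)
    msgs <- c(msgs, "bvecs must be a 3 x n matrix")
  if (ncol(object@bvecs) != length(object@bvals))
    msgs <- c(msgs, "bvals and bvecs must have one entry per volume")
  if (any(object@bvals < 0))
    msgs <- c(msgs, "b-values must be nonnegative")
  dwi <- object@bvals > 0
  if (any(dwi)) {
    nrm <- sqrt(colSums(object@bvecs[, dwi, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msgs <- c(msgs, "non-b0 gradient directions must have unit norm (1e-6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Integer region-label atlas
#'
#' A 3D integer label volume (0 = background, k > 0 = region k) together with
#' region names and the isotropic voxel size. All volumes of a cohort share
#' this grid.
#'
#' @slot labels integer 3D array of region labels.
#' @slot regionNames named character vector; names are the integer labels.
#' @slot voxelSize positive scalar, isotropic voxel edge in mm.
#' @export
setClass("RegionAtlas",
  slots = c(labels = "array", regionNames = "character", voxelSize = "numeric"))

setValidity("RegionAtlas", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  if (any(object@labels < 0) || any(object@labels != round(object@labels)))
    msgs <- c(msgs, "labels must be nonnegative integers")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msgs <- c(msgs, "voxelSize must be a positive scalar (mm)")
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  named <- sort(as.integer(names(object@regionNames)))
  if (!identical(labs, named))
    msgs <- c(msgs, "every named region must occupy >= 1 voxel and every label must be named")
  if (length(msgs)) msgs else TRUE
})

#' Per-voxel cell-count volumes for the six cell classes
#'
#' Named nonnegative 3D arrays (cells per voxel) for Cells, Neurons, Glia,
#' Oligodendrocytes, Astrocytes and Microglia, obeying the class hierarchy
#' Cells = Neurons + Glia and Glia = Oligodendrocytes + Astrocytes +
#' Microglia elementwise.
#'
#' @slot counts named list of 3D arrays, one per cell class.
#' @export
setClass("CellCountVolumeSet", slots = c(counts = "list"))

setValidity("CellCountVolumeSet", function(object) {
  msgs <- character()
  cts <- object@counts
  if (!all(.CELLTYPES %in% names(cts)))
    return(paste("counts must contain:", paste(.CELLTYPES, collapse = ", ")))
  dims <- lapply(cts, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    msgs <- c(msgs, "all count volumes must share one grid")
  for (ct in .CELLTYPES)
    if (any(cts[[ct]] < 0)) msgs <- c(msgs, paste0(ct, " has negative counts"))
  tol <- 1e-8 * (1 + max(abs(cts$Cells)))
  if (max(abs(cts$Glia - (cts$Oligodendrocytes + cts$Astrocytes + cts$Microglia))) > tol)
    msgs <- c(msgs, "Glia must equal Oligodendrocytes + Astrocytes + Microglia")
  if (max(abs(cts$Cells - (cts$Neurons + cts$Glia))) > tol)
    msgs <- c(msgs, "Cells must equal Neurons + Glia")
  if (length(msgs)) msgs else TRUE
})

#' Per-voxel diffusion metric volumes
#'
#' Named arrays for (a subset of) the six diffusion metrics: AD, ADC, RD in
#' um^2/ms; FA, NDI, ODI dimensionless in \[0, 1\]. A set derived from a
#' tensor fit carries only AD, ADC, FA, RD.
#'
#' @slot metrics named list of numeric arrays on one shared grid.
#' @export
setClass("MetricVolumeSet", slots = c(metrics = "list"))

setValidity("MetricVolumeSet", function(object) {
  msgs <- character()
  m <- object@metrics
  if (length(m) == 0L || is.null(names(m)) || !all(names(m) %in% .METRICS))
    return("metrics must be named among AD, ADC, FA, RD, NDI, ODI")
  dims <- lapply(m, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    msgs <- c(msgs, "all metric volumes must share one grid")
  for (nm in intersect(c("FA", "NDI", "ODI"), names(m))) {
    v <- m[[nm]][is.finite(m[[nm]])]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      msgs <- c(msgs, paste0(nm, " must lie in [0, 1]"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Phantom cohort specification
#'
#' Encodes the generative conditions of a synthetic cohort: number of
#' subjects, per-region affine relationships mapping cell-count fields to
#' diffusion metrics, per-metric noise levels, subject misalignment jitter,
#' count-field texture, and the seed that makes generation a pure function.
#'
#' @slot nSubjects integer >= 2.
#' @slot relationships named list (one entry per region name); each entry a
#'   named list over metrics of `list(intercept =, slopes = c(<cell type> = ...))`.
#' @slot noiseSd named numeric, per-metric additive noise sd (metric units).
#' @slot jitterSd nonnegative scalar, smooth displacement magnitude (voxels).
#' @slot jitterSigma smoothness (voxels) of the displacement field.
#' @slot countFieldSigma smoothness (voxels) of the latent count fields.
#' @slot baselines named list per region: named numeric baseline density per
#'   base cell type (Neurons, Oligodendrocytes, Astrocytes, Microglia).
#' @slot amplitudes named numeric, sd of the smooth fluctuation of each base
#'   cell type's count field (cells/voxel).
#' @slot metricBaselines named numeric, metric value used where no
#'   relationship term applies (background and unlisted metrics).
#' @slot seed integer master seed of the generator.
#' @export
setClass("CohortSpec",
  slots = c(nSubjects = "integer", relationships = "list",
            noiseSd = "numeric", jitterSd = "numeric", jitterSigma = "numeric",
            countFieldSigma = "numeric", baselines = "list",
            amplitudes = "numeric", metricBaselines = "numeric",
            seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nSubjects < 2L) msgs <- c(msgs, "nSubjects must be >= 2")
  if (any(object@noiseSd < 0)) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@jitterSd < 0) msgs <- c(msgs, "jitterSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A generated phantom cohort
#'
#' Bundles the atlas, the per-subject metric and count volume sets, the
#' shared reference (jitter-free, noise-free) counts, and the generating
#' specification. Subject order is stable.
#'
#' @slot atlas [RegionAtlas-class].
#' @slot metricSets list of [MetricVolumeSet-class], one per subject.
#' @slot countSets list of [CellCountVolumeSet-class], one per subject.
#' @slot referenceCounts [CellCountVolumeSet-class] shared across subjects.
#' @slot spec [CohortSpec-class].
#' @export
setClass("Cohort",
  slots = c(atlas = "RegionAtlas", metricSets = "list", countSets = "list",
            referenceCounts = "CellCountVolumeSet", spec = "CohortSpec"))

setValidity("Cohort", function(object) {
  msgs <- character()
  n <- object@spec@nSubjects
  if (length(object@metricSets) != n || length(object@countSets) != n)
    msgs <- c(msgs, "one MetricVolumeSet and one CellCountVolumeSet per subject required")
  d0 <- dim(object@atlas@labels)
  for (s in seq_along(object@metricSets)) {
    if (!identical(as.integer(dim(object@metricSets[[s]]@metrics[[1]])), as.integer(d0)))
      msgs <- c(msgs, "all volumes must share the atlas grid")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted diffusion tensor volume
#'
#' Six unique tensor components per voxel (um^2/ms) plus the fitted log
#' baseline signal. Component order is Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#'
#' @slot comps n x 6 numeric matrix of tensor components.
#' @slot logS0 numeric vector of fitted log s0 per voxel.
#' @slot spatialDim integer spatial dimensions of the source volume, or
#'   `NA` when fitted from a plain voxel list.
#' @export
setClass("TensorVolume",
  slots = c(comps = "matrix", logS0 = "numeric", spatialDim = "integer"))

setValidity("TensorVolume", function(object) {
  if (ncol(object@comps) != 6L) return("comps must have 6 columns")
  if (nrow(object@comps) != length(object@logS0))
    return("one logS0 per voxel required")
  TRUE
})

#' Cubic block partition of a masked grid
#'
#' The grid is tiled from array index (1,1,1) into factor^3 cubes; retained
#' blocks (enough in-mask voxels) get unique labels 1..K in lexicographic
#' cube order. `cubeIndex` keeps the global cube index of each block so
#' partitions of different masks on one grid are comparable.
#'
#' @slot labels integer 3D array; 0 outside retained blocks.
#' @slot factor block edge length in voxels.
#' @slot blockIds integer vector 1..K.
#' @slot cubeIndex integer vector, global cube index per block.
#' @export
setClass("BlockPartition",
  slots = c(labels = "array", factor = "integer", blockIds = "integer",
            cubeIndex = "integer"))

setValidity("BlockPartition", function(object) {
  ids <- object@blockIds
  if (!identical(ids, seq_along(ids))) return("blockIds must be contiguous from 1")
  if (length(object@cubeIndex) != length(ids))
    return("one cubeIndex per block required")
  TRUE
})

#' Group correlation matrix for one region
#'
#' Long-format table of the 36 metric x cell-type pairs: per-subject Pearson
#' r, mean Fisher Z, one-sample t, df, raw and Holm-Sidak-adjusted p, and
#' the significance flag at the chosen alpha.
#'
#' @slot table data.frame, one row per (metric, cell type) pair.
#' @slot region character region name.
#' @slot nSubjects integer.
#' @slot alpha numeric significance threshold on adjusted p.
#' @slot factor integer regridding factor used.
#' @export
setClass("CorrelationMatrix",
  slots = c(table = "data.frame", region = "character", nSubjects = "integer",
            alpha = "numeric", factor = "integer"))

#' Trained autoencoder feature compressor
#'
#' A fully-connected autoencoder (linear, or with tanh hidden layers)
#' trained by Adam on standardized metric features to minimize
#' reconstruction MSE; the encoder maps 6 metrics to `latentDim` features.
#'
#' @slot layers list of `list(W, b, act)` for encoder then decoder.
#' @slot nEncoderLayers integer, how many leading layers form the encoder.
#' @slot center,scale numeric standardization statistics (training data).
#' @slot latentDim integer.
#' @slot finalLoss numeric training reconstruction MSE.
#' @export
setClass("Compressor",
  slots = c(layers = "list", nEncoderLayers = "integer", center = "numeric",
            scale = "numeric", latentDim = "integer", finalLoss = "numeric"))

#' Prediction result for one cell type in one region
#'
#' Reference (atlas) and predicted block counts (predictions averaged over
#' the leave-one-subject-out trials), with Pearson R, its two-sided p, the
#' predicted-vs-reference regression line, and optional bootstrap R/p
#' distributions.
#'
#' @slot cellType,region character.
#' @slot blockId integer vector of retained blocks.
#' @slot reference,predicted numeric vectors, one value per block.
#' @slot bySubject numeric matrix (blocks x subjects) of fold predictions.
#' @slot R,p,slope,intercept numeric scalars.
#' @slot bootstrap data.frame with columns R, p, slope, intercept (0 rows if
#'   no bootstrap was run).
#' @slot config list snapshot of the configuration used.
#' @export
setClass("PredictionResult",
  slots = c(cellType = "character", region = "character", blockId = "integer",
            reference = "numeric", predicted = "numeric", bySubject = "matrix",
            R = "numeric", p = "numeric", slope = "numeric",
            intercept = "numeric", bootstrap = "data.frame", config = "list"))

setValidity("PredictionResult", function(object) {
  msgs <- character()
  if (length(object@reference) != length(object@predicted))
    msgs <- c(msgs, "reference and predicted must have equal length")
  if (is.finite(object@R) && abs(object@R) > 1 + 1e-12)
    msgs <- c(msgs, "|R| must be <= 1")
  if (length(msgs)) msgs else TRUE
})
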