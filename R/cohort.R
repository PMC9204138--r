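#' Construct a phantom cohort specification
#'
#' The specification fixes every generative condition of a synthetic cohort;
#' [makeCohort()] is then a pure function of (atlas, spec). Defaults emulate
#' a six-subject ex vivo mouse study: smooth nonnegative cell-count fields
#' with region-specific baselines, region-specific affine metric/count
#' relationships, per-metric additive noise, and a smooth sub-voxel
#' misalignment jitter standing in for residual registration error.
#'
#' @param atlas a [RegionAtlas-class]; used to default per-region entries.
#' @param nSubjects number of subjects (default 6).
#' @param relationships per-region metric models; see
#'   [defaultRelationships()]. Must contain an entry for every region.
#' @param noiseSd named per-metric noise sd in metric units.
#' @param jitterSd magnitude (voxels) of the smooth per-subject displacement
#'   field (default 0.5 voxels).
#' @param jitterSigma smoothness (voxels) of the displacement field.
#' @param countFieldSigma smoothness (voxels) of the latent count fields.
#' @param baselines per-region named baseline densities (cells/voxel) for
#'   the four base cell types; defaults give each region a distinct tissue
#'   character.
#' @param amplitudes named sd (cells/voxel) of each base type's smooth
#'   spatial fluctuation.
#' @param metricBaselines named metric values used where no relationship
#'   applies.
#' @param seed master seed of the generator.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(atlas,
                       nSubjects = 6L,
                       relationships = defaultRelationships(atlas),
                       noiseSd = c(AD = 0.04, ADC = 0.03, FA = 0.02,
                                   RD = 0.03, NDI = 0.02, ODI = 0.02),
                       jitterSd = 0.5,
                       jitterSigma = 4,
                       countFieldSigma = 3,
                       baselines = defaultBaselines(atlas),
                       amplitudes = c(Neurons = 40, Oligodendrocytes = 12,
                                      Astrocytes = 14, Microglia = 9),
                       metricBaselines = c(AD = 1.1, ADC = 0.7, FA = 0.35,
                                           RD = 0.5, NDI = 0.5, ODI = 0.4),
                       seed = 1L) {
  noiseSd <- noiseSd[.METRICS]
  names(noiseSd) <- .METRICS
  noiseSd[is.na(noiseSd)] <- 0
  if (isTRUE(attr(relationships, "centerAtBaseline")))
    relationships <- .centerRelationships(relationships, baselines)
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      relationships = relationships, noiseSd = noiseSd,
      jitterSd = jitterSd, jitterSigma = jitterSigma,
      countFieldSigma = countFieldSigma, baselines = baselines,
      amplitudes = amplitudes, metricBaselines = metricBaselines,
      seed = as.integer(seed))
}

# Aggregate a region's base-type baselines to all six cell classes.
.aggBaselines <- function(b) {
  glia <- b[["Oligodendrocytes"]] + b[["Astrocytes"]] + b[["Microglia"]]
  c(Cells = b[["Neurons"]] + glia, Neurons = b[["Neurons"]], Glia = glia,
    Oligodendrocytes = b[["Oligodendrocytes"]],
    Astrocytes = b[["Astrocytes"]], Microglia = b[["Microglia"]])
}

# Re-anchor intercepts so each metric sits at its stated intercept when the
# counts sit at the region's baseline: intercept' = intercept -
# sum(slope * baseline count). This keeps metric distributions overlapping
# across regions of opposite slope sign, so region identity cannot be read
# off the metric level alone.
.centerRelationships <- function(relationships, baselines) {
  for (r in names(relationships)) {
    agg <- .aggBaselines(baselines[[r]])
    for (m in names(relationships[[r]])) {
      sl <- relationships[[r]][[m]]$slopes
      if (length(sl))
        relationships[[r]][[m]]$intercept <-
          relationships[[r]][[m]]$intercept - sum(sl * agg[names(sl)])
    }
  }
  attr(relationships, "centerAtBaseline") <- NULL
  relationships
}

#' Default region-specific metric/count relationships
#'
#' Each region gets an affine model per metric, `metric = intercept +
#' sum(slope * count) + noise`, with signs alternating between consecutive
#' regions so that neighbouring regions show opposite metric/count
#' relationships (the situation a pooled whole-brain model cannot learn).
#' The stated intercept is interpreted as the metric value at the region's
#' baseline counts ([cohortSpec()] re-anchors the raw intercept
#' accordingly), so regions of opposite sign still have overlapping metric
#' distributions. Effect sizes are calibration choices: slopes are scaled
#' so the count-driven metric variation is a few times the default noise
#' sd.
#'
#' @param atlas a [RegionAtlas-class].
#' @param signs optional numeric vector (+1/-1) per region overriding the
#'   alternating default.
#' @return Named list over regions, each a named list over metrics of
#'   `list(intercept =, slopes = c(<cell type> = slope))`.
#' @export
defaultRelationships <- function(atlas, signs = NULL) {
  nms <- atlas@regionNames
  if (is.null(signs)) signs <- (-1)^(seq_along(nms) + 1)
  stopifnot(length(signs) == length(nms))
  out <- lapply(seq_along(nms), function(k) {
    s <- signs[k]
    list(
      FA  = list(intercept = 0.35, slopes = c(Glia = s * 0.0030)),
      NDI = list(intercept = 0.50, slopes = c(Neurons = s * 0.0015)),
      ADC = list(intercept = 0.70, slopes = c(Cells = -s * 0.0012)),
      AD  = list(intercept = 1.10, slopes = c(Oligodendrocytes = -s * 0.0040)),
      RD  = list(intercept = 0.50, slopes = c(Cells = -s * 0.0008)),
      ODI = list(intercept = 0.40, slopes = c(Microglia = s * 0.0040)))
  })
  names(out) <- nms
  attr(out, "centerAtBaseline") <- TRUE
  out
}

#' Relationships with no metric/count dependence (full null)
#'
#' @rdname defaultRelationships
#' @export
nullRelationships <- function(atlas) {
  nms <- atlas@regionNames
  out <- lapply(nms, function(nm) {
    stats::setNames(lapply(.METRICS, function(m)
      list(intercept = c(AD = 1.1, ADC = 0.7, FA = 0.35, RD = 0.5,
                         NDI = 0.5, ODI = 0.4)[[m]],
           slopes = numeric(0))), .METRICS)
  })
  names(out) <- nms
  out
}

#' @rdname defaultRelationships
#' @export
defaultBaselines <- function(atlas) {
  nms <- atlas@regionNames
  # distinct tissue characters: cycle neuron-rich / glia-rich / mixed
  presets <- list(
    c(Neurons = 200, Oligodendrocytes = 40, Astrocytes = 50, Microglia = 30),
    c(Neurons = 60, Oligodendrocytes = 120, Astrocytes = 60, Microglia = 25),
    c(Neurons = 130, Oligodendrocytes = 70, Astrocytes = 55, Microglia = 28))
  out <- lapply(seq_along(nms), function(k) presets[[(k - 1) %% 3 + 1]])
  names(out) <- nms
  out
}

# Unit-sd smooth Gaussian random field.
.smoothField <- function(dims, sigma, seed) {
  z <- withSeed(seed, array(stats::rnorm(prod(dims)), dim = dims))
  z <- gaussianSmooth3d(z, sigma)
  z / stats::sd(z)
}

#' Generate a phantom cohort
#'
#' Draws smooth nonnegative count fields for the four base cell types
#' (region-specific baseline + smooth fluctuation, clipped at 0), sums them
#' into the aggregate classes so the hierarchy Cells = Neurons + Glia and
#' Glia = Oligodendrocytes + Astrocytes + Microglia holds exactly, applies a
#' smooth per-subject displacement jitter, and maps counts to diffusion
#' metrics through the per-region affine relationships plus i.i.d. noise.
#' The reference counts are the jitter-free, noise-free fields. Generation
#' is a pure function of `spec@seed`.
#'
#' @param atlas a [RegionAtlas-class].
#' @param spec a [CohortSpec-class]; every atlas region must have a
#'   relationships entry.
#' @return A [Cohort-class].
#' @export
makeCohort <- function(atlas, spec) {
  dims <- dim(atlas@labels)
  nms <- atlas@regionNames
  if (!all(nms %in% names(spec@relationships)))
    stop("relationships missing for region(s): ",
         paste(setdiff(nms, names(spec@relationships)), collapse = ", "))
  for (r in nms) {
    rel <- spec@relationships[[r]]
    bad <- setdiff(names(rel), .METRICS)
    if (length(bad)) stop("unknown metric in relationships: ", bad[1])
    for (m in names(rel)) {
      badc <- setdiff(names(rel[[m]]$slopes), .CELLTYPES)
      if (length(badc)) stop("unknown cell type in relationships: ", badc[1])
    }
  }

  # reference count fields (shared "atlas counts")
  base <- list()
  for (bt in .BASETYPES) {
    bmap <- array(0, dim = dims)
    for (r in nms) {
      lab <- as.integer(names(nms)[match(r, nms)])
      bmap[atlas@labels == lab] <- spec@baselines[[r]][[bt]]
    }
    z <- .smoothField(dims, spec@countFieldSigma,
                      seedFrom(spec@seed, paste0("counts-", bt)))
    base[[bt]] <- pmax(bmap + spec@amplitudes[[bt]] * z, 0)
  }
  aggregate <- function(b) {
    glia <- b$Oligodendrocytes + b$Astrocytes + b$Microglia
    list(Cells = b$Neurons + glia, Neurons = b$Neurons, Glia = glia,
         Oligodendrocytes = b$Oligodendrocytes, Astrocytes = b$Astrocytes,
         Microglia = b$Microglia)
  }
  refCounts <- new("CellCountVolumeSet", counts = aggregate(base))

  ai <- arrayInd(seq_len(prod(dims)), dims)
  metricSets <- vector("list", spec@nSubjects)
  countSets <- vector("list", spec@nSubjects)
  for (s in seq_len(spec@nSubjects)) {
    # subject counts: reference fields sampled through a smooth displacement
    if (spec@jitterSd > 0) {
      u <- lapply(1:3, function(ax)
        spec@jitterSd * .smoothField(dims, spec@jitterSigma,
          seedFrom(spec@seed, paste0("jitter-s", s, "-ax", ax))))
      xs <- ai[, 1] + as.vector(u[[1]])
      ys <- ai[, 2] + as.vector(u[[2]])
      zs <- ai[, 3] + as.vector(u[[3]])
      subjBase <- lapply(base, function(v)
        array(trilinearSample(v, xs, ys, zs), dim = dims))
    } else {
      subjBase <- base
    }
    countSets[[s]] <- new("CellCountVolumeSet", counts = aggregate(subjBase))
    subjCounts <- countSets[[s]]@counts

    mets <- list()
    for (m in .METRICS) {
      vol <- array(spec@metricBaselines[[m]], dim = dims)
      for (r in nms) {
        lab <- as.integer(names(nms)[match(r, nms)])
        rel <- spec@relationships[[r]][[m]]
        if (is.null(rel)) next
        inr <- atlas@labels == lab
        v <- rep(rel$intercept, sum(inr))
        for (ct in names(rel$slopes))
          v <- v + rel$slopes[[ct]] * subjCounts[[ct]][inr]
        vol[inr] <- v
      }
      sdm <- spec@noiseSd[[m]]
      if (sdm > 0) {
        eps <- withSeed(seedFrom(spec@seed, paste0("noise-s", s, "-", m)),
                        array(stats::rnorm(prod(dims), sd = sdm), dim = dims))
        vol <- vol + eps
      }
      if (m %in% c("FA", "NDI", "ODI")) vol <- pmin(pmax(vol, 0), 1)
      mets[[m]] <- vol
    }
    metricSets[[s]] <- new("MetricVolumeSet", metrics = mets)
  }
  new("Cohort", atlas = atlas, metricSets = metricSets,
      countSets = countSets, referenceCounts = refCounts, spec = spec)
}
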