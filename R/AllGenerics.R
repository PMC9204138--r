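# Generics and accessors. Slot access from user code should go through these.

#' @rdname RegionAtlas-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname RegionAtlas-class
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' @rdname RegionAtlas-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname Cohort-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname Cohort-class
#' @param subject integer subject index.
#' @param metric metric name (one of AD, ADC, FA, RD, NDI, ODI).
#' @export
setGeneric("metricVolume", function(x, subject, metric) standardGeneric("metricVolume"))

#' @rdname Cohort-class
#' @param cellType cell class name.
#' @param reference logical; return the shared reference counts instead of a
#'   subject's (jittered) counts.
#' @export
setGeneric("countVolume", function(x, subject, cellType, reference = FALSE)
  standardGeneric("countVolume"))

#' @rdname Compressor-class
#' @param newdata numeric matrix (rows = observations, 6 metric columns).
#' @export
setGeneric("encode", function(x, newdata) standardGeneric("encode"))

#' @rdname RegionAtlas-class
setMethod("regionNames", "RegionAtlas", function(x) x@regionNames)

#' @rdname RegionAtlas-class
setMethod("atlasLabels", "RegionAtlas", function(x) x@labels)

#' @rdname RegionAtlas-class
setMethod("voxelSize", "RegionAtlas", function(x) x@voxelSize)

#' @rdname Cohort-class
setMethod("nSubjects", "Cohort", function(x) x@spec@nSubjects)

#' @rdname Cohort-class
setMethod("metricVolume", "Cohort", function(x, subject, metric) {
  stopifnot(subject >= 1, subject <= nSubjects(x), metric %in% .METRICS)
  x@metricSets[[subject]]@metrics[[metric]]
})

#' @rdname Cohort-class
setMethod("countVolume", "Cohort", function(x, subject, cellType, reference = FALSE) {
  stopifnot(cellType %in% .CELLTYPES)
  if (reference) return(x@referenceCounts@counts[[cellType]])
  stopifnot(subject >= 1, subject <= nSubjects(x))
  x@countSets[[subject]]@counts[[cellType]]
})

setMethod("show", "RegionAtlas", function(object) {
  d <- dim(object@labels)
  cat("RegionAtlas:", paste(d, collapse = " x "), "voxels @",
      object@voxelSize, "mm\n")
  for (lab in names(object@regionNames)) {
    n <- sum(object@labels == as.integer(lab))
    cat(sprintf("  region %s (%s): %d voxels\n", lab, object@regionNames[[lab]], n))
  }
})

setMethod("show", "GradientScheme", function(object) {
  tb <- table(object@bvals)
  cat("GradientScheme:", length(object@bvals), "volumes;",
      paste(sprintf("b=%s (%d)", names(tb), as.integer(tb)), collapse = ", "),
      "s/mm^2\n")
})

setMethod("show", "Cohort", function(object) {
  cat("Cohort of", nSubjects(object), "subjects on a",
      paste(dim(object@atlas@labels), collapse = " x "), "grid\n")
  cat("  regions:", paste(object@atlas@regionNames, collapse = ", "), "\n")
  cat("  jitterSd:", object@spec@jitterSd, "voxels; seed:", object@spec@seed, "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix for region", object@region,
      sprintf("(n = %d subjects, factor = %d, alpha = %g)\n",
              object@nSubjects, object@factor, object@alpha))
  tmat <- tapply(object@table$t, list(object@table$metric, object@table$cell_type),
                 identity)
  print(round(tmat[.METRICS[.METRICS %in% rownames(tmat)],
                   .CELLTYPES[.CELLTYPES %in% colnames(tmat)], drop = FALSE], 2))
  sig <- sum(object@table$significant, na.rm = TRUE)
  cat(sig, "of", nrow(object@table), "pairs significant after Holm-Sidak\n")
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %s in %s\n", object@cellType, object@region))
  cat(sprintf("  %d blocks; R = %.3f (p = %.3g), fit: pred = %.3f * ref + %.3f\n",
              length(object@blockId), object@R, object@p,
              object@slope, object@intercept))
  if (nrow(object@bootstrap))
    cat(sprintf("  bootstrap (%d iters): median R = %.3f\n",
                nrow(object@bootstrap), stats::median(object@bootstrap$R)))
})

setMethod("show", "Compressor", function(object) {
  cat(sprintf("Compressor: 6 -> %d (final training MSE %.4g)\n",
              object@latentDim, object@finalLoss))
})
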