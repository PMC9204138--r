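# End-to-end orchestration: simulate -> regrid -> correlate -> predict ->
# report, from one validated config with provenance sidecars.

.TOP_KEYS <- c("cohort", "regrid", "regions", "cellTypes", "alpha",
               "predictor", "out", "seed")
.COHORT_KEYS <- c("shape", "regions", "nSubjects", "noiseSd", "jitterSd",
                  "jitterSigma", "countFieldSigma", "voxelSize",
                  "relationshipSigns")
.REGRID_KEYS <- c("factor", "candidates", "erodeIters", "minFill")
.PRED_KEYS <- c("latentDim", "hidden", "epochs", "lr", "numTrees", "mtry",
                "minNodeSize", "cvFolds", "bootstrapIters", "subsampleFrac")

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("validation: unknown key(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Validate a pipeline run configuration
#'
#' Rejects unknown keys anywhere in the config and normalizes defaults
#' before any computation runs. See `inst/extdata/demo_config.yaml` for the
#' layout.
#'
#' @param config a named list, or the path of a YAML file.
#' @return The normalized config list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("validation: config must be a named list")
  .checkKeys(config, .TOP_KEYS, "config")
  co <- config$cohort %||% list()
  .checkKeys(co, .COHORT_KEYS, "cohort")
  rg <- config$regrid %||% list()
  .checkKeys(rg, .REGRID_KEYS, "regrid")
  pd <- config$predictor %||% list()
  .checkKeys(pd, .PRED_KEYS, "predictor")
  if (is.null(co$shape)) stop("validation: cohort$shape is required")
  if (is.null(co$regions)) stop("validation: cohort$regions is required")
  for (rn in names(co$regions)) {
    rr <- co$regions[[rn]]
    .checkKeys(rr, c("lower", "upper", "mirror"), paste0("region ", rn))
    if (is.null(rr$lower) || is.null(rr$upper))
      stop("validation: region ", rn, " needs lower and upper")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config$regions <- config$regions %||% names(co$regions)
  config$cellTypes <- config$cellTypes %||% .CELLTYPES
  if (!all(config$cellTypes %in% .CELLTYPES))
    stop("validation: unknown cell type(s): ",
         paste(setdiff(config$cellTypes, .CELLTYPES), collapse = ", "))
  if (is.null(config$out)) stop("validation: out directory is required")
  config
}

.buildAtlasFromConfig <- function(co) {
  layout <- lapply(co$regions, function(rr)
    cuboidRegion(unlist(rr$lower), unlist(rr$upper), isTRUE(rr$mirror)))
  names(layout) <- names(co$regions)
  makeAtlas(unlist(co$shape), layout, voxelSize = co$voxelSize %||% 0.125)
}

.buildSpecFromConfig <- function(atlas, co, seed) {
  args <- list(atlas = atlas, seed = seedFrom(seed, "cohort"))
  if (!is.null(co$nSubjects)) args$nSubjects <- co$nSubjects
  if (!is.null(co$noiseSd)) args$noiseSd <- unlist(co$noiseSd)
  if (!is.null(co$jitterSd)) args$jitterSd <- co$jitterSd
  if (!is.null(co$jitterSigma)) args$jitterSigma <- co$jitterSigma
  if (!is.null(co$countFieldSigma)) args$countFieldSigma <- co$countFieldSigma
  if (!is.null(co$relationshipSigns))
    args$relationships <- defaultRelationships(atlas,
                                               unlist(co$relationshipSigns))
  do.call(cohortSpec, args)
}

#' Run the full analysis pipeline from a config
#'
#' Executes, in order: phantom cohort simulation, block-factor selection
#' (or a fixed factor), per-region group correlation matrices, and
#' per-region/per-cell-type leave-one-subject-out prediction (optionally
#' with bootstrap distributions). Every artifact is written under the
#' configured output directory with a provenance sidecar (config hash +
#' seed); outputs contain no timestamps, so identical config + seed gives
#' byte-identical files.
#'
#' @param config named list or YAML path; see [validateRunConfig()].
#' @return Invisible run report: paths of all artifacts plus summary
#'   statistics per region/cell type.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(out = out, seed = seed, artifacts = character(0),
                 correlations = list(), predictions = list())
  addArtifact <- function(p) report$artifacts <<- c(report$artifacts, p)

  stage <- "simulate"
  res <- tryCatch({
    atlas <- .buildAtlasFromConfig(config$cohort)
    spec <- .buildSpecFromConfig(atlas, config$cohort, seed)
    cohort <- makeCohort(atlas, spec)
    writeProvenance(file.path(out, "cohort_provenance.json"),
                    config$cohort, seed, "simulate")
    addArtifact(file.path(out, "cohort_provenance.json"))

    stage <- "regrid"
    rg <- config$regrid %||% list()
    erodeIters <- rg$erodeIters %||% 3L
    minFill <- rg$minFill %||% 0.5
    if (!is.null(rg$factor)) {
      factor <- as.integer(rg$factor)
      scores <- stats::setNames(NA_real_, factor)
    } else {
      cand <- as.integer(unlist(rg$candidates %||% seq(10L, 50L, 5L)))
      opt <- optimizeBlockFactor(cohort, candidates = cand,
                                 erodeIters = erodeIters, minFill = minFill)
      factor <- opt$factor
      scores <- opt$scores
    }
    fpath <- file.path(out, "block_factor.json")
    jsonlite::write_json(list(factor = factor, scores = as.list(scores)),
                         fpath, auto_unbox = TRUE, digits = NA, na = "null")
    addArtifact(fpath)

    stage <- "correlate"
    for (rg_ in config$regions) {
      cm <- regionCorrelationMatrix(cohort, rg_, factor,
                                    alpha = config$alpha,
                                    erodeIters = erodeIters,
                                    minFill = minFill)
      csv <- file.path(out, paste0("correlation_", rg_, ".csv"))
      js <- file.path(out, paste0("correlation_", rg_, ".json"))
      writeCorrelationMatrix(cm, csv, js)
      addArtifact(c(csv, js))
      report$correlations[[rg_]] <-
        list(significant = sum(cm@table$significant, na.rm = TRUE))
    }

    stage <- "predict"
    pd <- config$predictor %||% list()
    comp <- compressorConfig(latentDim = pd$latentDim %||% 3L,
                             hidden = as.integer(unlist(pd$hidden %||% integer(0))),
                             epochs = pd$epochs %||% 300L,
                             lr = pd$lr %||% 0.02)
    grid <- expand.grid(num.trees = as.integer(unlist(pd$numTrees %||% c(250L, 1000L))),
                        mtry = as.integer(unlist(pd$mtry %||% c(1L, comp$latentDim))),
                        min.node.size = as.integer(unlist(pd$minNodeSize %||% c(1L, 5L))))
    grid <- grid[order(grid$num.trees, -grid$min.node.size, grid$mtry), ]
    for (rg_ in config$regions) {
      for (ctype in config$cellTypes) {
        pr <- looEvaluate(cohort, rg_, ctype, factor, compressor = comp,
                          grid = grid, cvFolds = pd$cvFolds %||% 5L,
                          erodeIters = erodeIters, minFill = minFill,
                          seed = seedFrom(seed, paste0("pred-", rg_, "-", ctype)))
        nIter <- pd$bootstrapIters %||% 0L
        if (nIter > 0) {
          pr@bootstrap <- bootstrapPerformance(
            cohort, rg_, ctype, factor,
            subsampleFrac = pd$subsampleFrac %||% 0.8, nIter = nIter,
            compressor = comp, grid = grid, cvFolds = pd$cvFolds %||% 5L,
            erodeIters = erodeIters, minFill = minFill,
            seed = seedFrom(seed, paste0("boot-", rg_, "-", ctype)))
        }
        base <- file.path(out, paste0("prediction_", rg_, "_", ctype))
        writePredictionResult(pr, paste0(base, ".json"), paste0(base, ".csv"),
                              if (nIter > 0) paste0(base, "_bootstrap.csv"))
        addArtifact(c(paste0(base, ".json"), paste0(base, ".csv")))
        report$predictions[[paste(rg_, ctype, sep = "/")]] <-
          list(R = pr@R, p = pr@p, slope = pr@slope)
      }
    }
    report$factor <- factor
    report
  }, error = function(e) {
    if (grepl("^validation:", conditionMessage(e))) stop(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         " (artifacts so far kept in ", out, ")", call. = FALSE)
  })
  rpath <- file.path(out, "report.json")
  jsonlite::write_json(res, rpath, auto_unbox = TRUE, digits = NA, na = "null")
  # hash the analysis content, not the destination directory
  writeProvenance(file.path(out, "run_provenance.json"),
                  config[setdiff(names(config), "out")], seed, "run")
  invisible(res)
}
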