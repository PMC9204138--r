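# Leave-one-subject-out prediction, bootstrap performance distributions and
# hemisphere/region transfer validation.

# Two-sided p of a Pearson correlation via the t transform, df = n - 2.
# Block non-independence is a known limitation of this p-value.
.pearsonP <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tv <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tv), n - 2)
}

.predLine <- function(reference, predicted) {
  if (stats::sd(reference) == 0)
    return(c(slope = NA_real_, intercept = NA_real_))
  fit <- stats::lm.fit(cbind(1, reference), predicted)
  c(slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]))
}

# Region block tables for prediction: metric features + reference target.
.predictionTables <- function(cohort, region, factor, erodeIters, minFill) {
  mask <- erodeMask(regionMask(cohort@atlas, region), erodeIters)
  .cohortTables(cohort, mask, factor, minFill, counts = "reference")
}

#' Leave-one-subject-out prediction of a cell type's block counts
#'
#' For each fold, one subject is held out; an autoencoder compressor and a
#' grid-searched extremely-randomized-trees regressor are fitted on the
#' held-in subjects' block rows (features: the 6 metric block means;
#' target: the shared reference counts) and the held-out subject's blocks
#' are predicted. Each block's final prediction is the mean over the trials
#' in which it was predicted (one per subject), and Pearson R, its
#' two-sided p, and the predicted-vs-reference line are computed between
#' the reference counts and these averaged predictions.
#'
#' A structural leakage guard asserts on every fold that no (subject,
#' block) row is in both the training and the test set.
#'
#' @param cohort a [Cohort-class] (>= 2 subjects).
#' @param region region name/label (or vector of labels to pool).
#' @param cellType one of Cells, Neurons, Glia, Oligodendrocytes,
#'   Astrocytes, Microglia.
#' @param factor block edge length in voxels.
#' @param compressor a [compressorConfig()].
#' @param grid hyperparameter grid (default [defaultParamGrid()] on the
#'   latent features).
#' @param cvFolds inner CV folds of the grid search.
#' @param erodeIters,minFill regridding controls.
#' @param seed master seed; folds, weights and trees draw from named
#'   substreams of it.
#' @return A [PredictionResult-class].
#' @export
looEvaluate <- function(cohort, region, cellType, factor,
                        compressor = compressorConfig(),
                        grid = NULL, cvFolds = 5L,
                        erodeIters = 3L, minFill = 0.5, seed = 1L) {
  stopifnot(cellType %in% .CELLTYPES)
  ct <- .predictionTables(cohort, region, factor, erodeIters, minFill)
  tables <- ct$tables
  n <- length(tables)
  nb <- nrow(tables[[1]])
  if (nb < 3) stop("region retains only ", nb, " blocks at factor ", factor)
  if (is.null(grid)) grid <- defaultParamGrid(compressor$latentDim)
  rowTag <- function(s) paste0("s", s, "-b", tables[[s]]$block_id)
  pred <- matrix(NA_real_, nb, n)
  for (s in seq_len(n)) {
    trainIdx <- setdiff(seq_len(n), s)
    trainTags <- unlist(lapply(trainIdx, rowTag))
    stopifnot(length(intersect(trainTags, rowTag(s))) == 0)  # leakage guard
    trainX <- do.call(rbind, lapply(trainIdx, function(j)
      as.matrix(tables[[j]][, .METRICS])))
    trainY <- unlist(lapply(trainIdx, function(j) tables[[j]][[cellType]]))
    if (stats::sd(trainY) == 0)
      stop("fold ", s, ": constant target counts")
    comp <- tryCatch(
      fitCompressor(trainX, compressor,
                    seed = seedFrom(seed, paste0("fold", s, "-comp"))),
      error = function(e) stop("fold ", s, ": ", conditionMessage(e)))
    Ztr <- encode(comp, trainX)
    Zte <- encode(comp, as.matrix(tables[[s]][, .METRICS]))
    reg <- tryCatch(
      fitRegressor(Ztr, trainY, grid, cvFolds,
                   seed = seedFrom(seed, paste0("fold", s, "-reg"))),
      error = function(e) stop("fold ", s, ": ", conditionMessage(e)))
    pred[, s] <- .predictTrees(reg$model, Zte)
  }
  avg <- rowMeans(pred)
  ref <- tables[[1]][[cellType]]
  R <- stats::cor(ref, avg)
  line <- .predLine(ref, avg)
  regName <- if (is.numeric(region))
    paste(cohort@atlas@regionNames[as.character(region)], collapse = "+")
  else paste(region, collapse = "+")
  new("PredictionResult", cellType = cellType, region = regName,
      blockId = as.integer(tables[[1]]$block_id), reference = ref,
      predicted = avg, bySubject = pred, R = R, p = .pearsonP(R, nb),
      slope = line[["slope"]], intercept = line[["intercept"]],
      bootstrap = data.frame(), config = list(
        factor = factor, cellType = cellType, compressor = compressor,
        grid = grid, cvFolds = cvFolds, erodeIters = erodeIters,
        minFill = minFill, seed = seed))
}

# One subsampled LOO pass with fixed tree parameters; returns NULL when too
# few test rows survive the subsampling.
.bootstrapOnce <- function(tables, cellType, params, compressor,
                           subsampleFrac, seed) {
  n <- length(tables)
  nb <- nrow(tables[[1]])
  sums <- numeric(nb); cnt <- integer(nb)
  for (s in seq_len(n)) {
    trainIdx <- setdiff(seq_len(n), s)
    trainX <- do.call(rbind, lapply(trainIdx, function(j)
      as.matrix(tables[[j]][, .METRICS])))
    trainY <- unlist(lapply(trainIdx, function(j) tables[[j]][[cellType]]))
    ntr <- nrow(trainX)
    keepTr <- withSeed(seedFrom(seed, paste0("f", s, "-train")),
                       sort(sample(ntr, max(2, round(subsampleFrac * ntr)))))
    keepTe <- withSeed(seedFrom(seed, paste0("f", s, "-test")),
                       sort(sample(nb, max(1, round(subsampleFrac * nb)))))
    comp <- fitCompressor(trainX[keepTr, , drop = FALSE], compressor,
                          seed = seedFrom(seed, paste0("f", s, "-comp")))
    Ztr <- encode(comp, trainX[keepTr, , drop = FALSE])
    m <- .fitTrees(Ztr, trainY[keepTr], params,
                   seed = seedFrom(seed, paste0("f", s, "-trees")))
    Zte <- encode(comp, as.matrix(tables[[s]][keepTe, .METRICS]))
    pr <- .predictTrees(m, Zte)
    sums[keepTe] <- sums[keepTe] + pr
    cnt[keepTe] <- cnt[keepTe] + 1L
  }
  got <- cnt > 0
  if (sum(got) < 3) return(NULL)
  ref <- tables[[1]][[cellType]][got]
  avg <- sums[got] / cnt[got]
  R <- stats::cor(ref, avg)
  line <- .predLine(ref, avg)
  data.frame(R = R, p = .pearsonP(R, sum(got)),
             slope = line[["slope"]], intercept = line[["intercept"]])
}

#' Bootstrap distribution of prediction performance
#'
#' Tree hyperparameters are first chosen once for the region by the usual
#' grid search on the full data. Then, per iteration, the training and
#' testing rows of every leave-one-subject-out fold are independently
#' subsampled without replacement at `subsampleFrac` before fitting and
#' predicting, and the resulting Pearson R, p, and fit line are recorded.
#' Iterations whose surviving test rows number fewer than 3 are skipped and
#' redrawn (with a message).
#'
#' @inheritParams looEvaluate
#' @param subsampleFrac fraction of rows retained per iteration (default
#'   0.8; 0.7 reproduces the subsampling robustness check).
#' @param nIter number of iterations (default 1000).
#' @return data.frame with `nIter` rows and columns R, p, slope, intercept.
#' @export
bootstrapPerformance <- function(cohort, region, cellType, factor,
                                 subsampleFrac = 0.8, nIter = 1000L,
                                 compressor = compressorConfig(),
                                 grid = NULL, cvFolds = 5L,
                                 erodeIters = 3L, minFill = 0.5, seed = 1L) {
  stopifnot(subsampleFrac > 0, subsampleFrac <= 1, nIter >= 1)
  ct <- .predictionTables(cohort, region, factor, erodeIters, minFill)
  tables <- ct$tables
  if (nrow(tables[[1]]) < 3) stop("too few blocks at factor ", factor)
  if (is.null(grid)) grid <- defaultParamGrid(compressor$latentDim)
  allX <- do.call(rbind, lapply(tables, function(tb) as.matrix(tb[, .METRICS])))
  allY <- unlist(lapply(tables, `[[`, cellType))
  compAll <- fitCompressor(allX, compressor, seed = seedFrom(seed, "grid-comp"))
  params <- fitRegressor(encode(compAll, allX), allY, grid, cvFolds,
                         seed = seedFrom(seed, "grid-search"))$params
  out <- vector("list", nIter)
  draw <- 0L
  for (i in seq_len(nIter)) {
    res <- NULL
    while (is.null(res)) {
      draw <- draw + 1L
      res <- .bootstrapOnce(tables, cellType, params, compressor,
                            subsampleFrac, seedFrom(seed, paste0("iter", draw)))
      if (is.null(res))
        message("bootstrap iteration left <3 test rows; redrawn")
    }
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Transfer validation: train in one place, test in another
#'
#' Fits the full pipeline (compressor + grid-searched trees, all subjects
#' pooled) on the blocks of a source region/hemisphere and evaluates it on
#' the blocks of a disjoint target. Spatially overlapping source and target
#' block sets raise a leakage error.
#'
#' @inheritParams looEvaluate
#' @param train,test selectors: `list(region =, hemisphere = NULL)`;
#'   `hemisphere` is `"left"` or `"right"` (split across the mid-plane of
#'   array dimension 1).
#' @return `list(R, p, slope, intercept, nBlocks)`.
#' @export
transferEvaluate <- function(cohort, train, test, cellType, factor,
                             compressor = compressorConfig(),
                             grid = NULL, cvFolds = 5L,
                             erodeIters = 3L, minFill = 0.5, seed = 1L) {
  stopifnot(cellType %in% .CELLTYPES)
  selMask <- function(sel) {
    m <- regionMask(cohort@atlas, sel$region)
    if (!is.null(sel$hemisphere))
      m <- m & hemisphereMask(cohort@atlas, sel$hemisphere)
    erodeMask(m, erodeIters)
  }
  srcTabs <- .cohortTables(cohort, selMask(train), factor, minFill, "reference")
  tgtTabs <- .cohortTables(cohort, selMask(test), factor, minFill, "reference")
  if (length(intersect(srcTabs$partition@cubeIndex,
                       tgtTabs$partition@cubeIndex)))
    stop("training and testing block sets overlap (leakage)")
  if (nrow(tgtTabs$tables[[1]]) < 3) stop("target retains too few blocks")
  if (is.null(grid)) grid <- defaultParamGrid(compressor$latentDim)
  trainX <- do.call(rbind, lapply(srcTabs$tables, function(tb)
    as.matrix(tb[, .METRICS])))
  trainY <- unlist(lapply(srcTabs$tables, `[[`, cellType))
  comp <- fitCompressor(trainX, compressor, seed = seedFrom(seed, "xfer-comp"))
  reg <- fitRegressor(encode(comp, trainX), trainY, grid, cvFolds,
                      seed = seedFrom(seed, "xfer-reg"))
  n <- length(tgtTabs$tables)
  nb <- nrow(tgtTabs$tables[[1]])
  pred <- vapply(seq_len(n), function(s)
    .predictTrees(reg$model,
                  encode(comp, as.matrix(tgtTabs$tables[[s]][, .METRICS]))),
    numeric(nb))
  avg <- rowMeans(matrix(pred, nrow = nb))
  ref <- tgtTabs$tables[[1]][[cellType]]
  R <- stats::cor(ref, avg)
  line <- .predLine(ref, avg)
  list(R = R, p = .pearsonP(R, nb), slope = line[["slope"]],
       intercept = line[["intercept"]], nBlocks = nb)
}
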