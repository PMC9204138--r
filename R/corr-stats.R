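# Per-subject Pearson correlations over blocks, Fisher-Z aggregation with
# one-sample t-tests, and Holm-Sidak multiple-comparison correction.

#' Metric x cell-type Pearson correlation matrix for one subject
#'
#' Computes the product-moment correlation of every metric column against
#' every count column over the blocks of one subject's block table. Pairs
#' involving a constant column are undefined and returned as `NA` (they are
#' later dropped from the group test).
#'
#' @param table a block table (from [blockPartitionAndMeans()]) carrying
#'   metric and count columns; >= 3 blocks required.
#' @param metricCols,countCols column name vectors; default to the metrics
#'   and cell types present.
#' @return Numeric matrix (metrics x cell types) of Pearson r.
#' @export
subjectPairCorrelations <- function(table, metricCols = NULL, countCols = NULL) {
  if (is.null(metricCols)) metricCols <- intersect(.METRICS, colnames(table))
  if (is.null(countCols)) countCols <- intersect(.CELLTYPES, colnames(table))
  stopifnot(nrow(table) >= 3, length(metricCols) >= 1, length(countCols) >= 1)
  X <- as.matrix(table[, metricCols, drop = FALSE])
  Y <- as.matrix(table[, countCols, drop = FALSE])
  sdx <- apply(X, 2, stats::sd)
  sdy <- apply(Y, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X, Y))
  r[sdx == 0, ] <- NA_real_
  r[, sdy == 0] <- NA_real_
  r
}

#' Fisher Z transform of a correlation coefficient
#'
#' `z = atanh(r)`; correlations with |r| = 1 (noiseless data) are clipped to
#' +/- (1 - 1e-12) first so the transform stays finite.
#'
#' @param r numeric vector of correlations in \[-1, 1\].
#' @return Numeric vector of Z scores.
#' @export
fisherZ <- function(r) {
  stopifnot(all(abs(r[!is.na(r)]) <= 1 + 1e-12))
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' One-sample t-test of Fisher-Z-transformed correlations across subjects
#'
#' Transforms each subject's Pearson r with [fisherZ()] and tests the mean Z
#' against zero: `t = mean(z) / (sd(z) / sqrt(n))`, `df = n - 1`, two-sided
#' p from the t distribution. A degenerate sample (zero spread, nonzero
#' mean) reports t = +/-Inf with p = 0 and `degenerate = TRUE`.
#'
#' @param r numeric vector of per-subject correlations (NA entries dropped;
#'   >= 2 defined values required).
#' @return `list(t, df, p, meanZ, n, degenerate)`.
#' @export
groupCorrelationTest <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) < 2) stop("at least 2 subjects with defined r are required")
  z <- fisherZ(r)
  n <- length(z)
  s <- stats::sd(z)
  m <- mean(z)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, meanZ = 0, n = n,
                            degenerate = FALSE))
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, meanZ = m, n = n,
                degenerate = TRUE))
  }
  tval <- m / (s / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1),
       meanZ = m, n = n, degenerate = FALSE)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' With p-values sorted ascending, the i-th adjusted value is
#' `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, clipped at 1, returned in
#' the original order. Rejection at level `alpha` requires adjusted p <
#' `alpha`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param alpha significance threshold (default 0.05).
#' @return `list(adjusted, reject)` aligned with the input.
#' @export
holmSidak <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- cummax(pmin(1 - (1 - ps)^(m - seq_len(m) + 1), 1))
  out <- numeric(m)
  out[o] <- adj
  list(adjusted = out, reject = out < alpha)
}

#' Group correlation matrix of one region
#'
#' Composes the full voxel-wise correlation analysis for a region: erode
#' the region mask, partition into cubic blocks and average metrics and
#' counts per block, compute each subject's 6 x 6 Pearson matrix over
#' blocks, aggregate each pair across subjects with the Fisher-Z one-sample
#' t-test, and Holm-Sidak-correct the raw p-values over the pairs of this
#' one matrix (the correction family is the single region's matrix).
#'
#' Pairs undefined in some subjects are tested on the remaining subjects if
#' at least 2 remain, otherwise reported NA and excluded from the
#' correction family (with a warning).
#'
#' @param cohort a [Cohort-class].
#' @param region region name or label (or vector of labels to pool).
#' @param factor block edge length in voxels.
#' @param alpha significance threshold on adjusted p.
#' @param erodeIters erosion passes applied to the region mask.
#' @param minFill minimum block fill fraction.
#' @param counts which count fields to correlate against: the subjects' own
#'   (jittered) fields or the shared reference counts.
#' @return A [CorrelationMatrix-class].
#' @export
regionCorrelationMatrix <- function(cohort, region, factor, alpha = 0.05,
                                    erodeIters = 3L, minFill = 0.5,
                                    counts = c("subject", "reference")) {
  counts <- match.arg(counts)
  mask <- erodeMask(regionMask(cohort@atlas, region), erodeIters)
  ct <- .cohortTables(cohort, mask, factor, minFill, counts = counts)
  nblocks <- nrow(ct$tables[[1]])
  if (nblocks < 3)
    stop("region retains only ", nblocks,
         " blocks; use a smaller block factor")
  n <- nSubjects(cohort)
  rList <- lapply(ct$tables, subjectPairCorrelations)
  rows <- expand.grid(metric = .METRICS, cell_type = .CELLTYPES,
                      stringsAsFactors = FALSE)
  rMat <- vapply(seq_len(n), function(s)
    rList[[s]][cbind(rows$metric, rows$cell_type)], numeric(nrow(rows)))
  rMat <- matrix(rMat, nrow = nrow(rows))
  colnames(rMat) <- paste0("r_s", seq_len(n))
  res <- data.frame(rows, rMat, meanZ = NA_real_, t = NA_real_,
                    df = NA_real_, p_raw = NA_real_)
  for (i in seq_len(nrow(res))) {
    ri <- rMat[i, ]
    if (sum(!is.na(ri)) < 2) {
      warning("pair ", rows$metric[i], "/", rows$cell_type[i],
              " undefined in too many subjects; reported NA")
      next
    }
    g <- groupCorrelationTest(ri)
    res$meanZ[i] <- g$meanZ; res$t[i] <- g$t
    res$df[i] <- g$df; res$p_raw[i] <- g$p
  }
  res$p_adj <- NA_real_
  res$significant <- NA
  ok <- !is.na(res$p_raw)
  if (any(ok)) {
    hs <- holmSidak(res$p_raw[ok], alpha)
    res$p_adj[ok] <- hs$adjusted
    res$significant[ok] <- hs$reject
  }
  regName <- if (is.numeric(region))
    paste(cohort@atlas@regionNames[as.character(region)], collapse = "+")
  else paste(region, collapse = "+")
  new("CorrelationMatrix", table = res, region = regName,
      nSubjects = as.integer(n), alpha = alpha, factor = as.integer(factor))
}

#' Block-level full-null phantom tables
#'
#' Generates per-subject block tables whose metric and count columns are
#' independent Gaussian draws: the exact null of "no metric/count
#' relationship" at the block level, used to check family-wise error
#' control of the group correlation machinery.
#'
#' @param nBlocks,nSubjects table dimensions.
#' @param seed RNG seed.
#' @return List of `nSubjects` data.frames with `block_id`, 6 metric and 6
#'   count columns.
#' @export
makeNullTables <- function(nBlocks, nSubjects, seed = 1L) {
  withSeed(seed, lapply(seq_len(nSubjects), function(s) {
    tab <- data.frame(block_id = seq_len(nBlocks))
    for (m in .METRICS) tab[[m]] <- stats::rnorm(nBlocks)
    for (ct in .CELLTYPES) tab[[ct]] <- stats::rnorm(nBlocks)
    tab
  }))
}
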