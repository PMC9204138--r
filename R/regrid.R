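# Mask erosion, cubic block partitioning/averaging, and the inter-subject
# variance criterion used to select the block factor.

.shift3d <- function(x, ax, by) {
  # shift a logical array by `by` along axis `ax`, padding with FALSE
  d <- dim(x)
  out <- array(FALSE, dim = d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[ax]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[ax]] <- (1 + by):n; src[[ax]] <- 1:(n - by) }
  if (by < 0) { dst[[ax]] <- 1:(n + by); src[[ax]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological erosion of a binary mask
#'
#' Applies `iterations` passes of one-voxel erosion with a 6-connected
#' structuring element (a voxel survives if it and all six face neighbours
#' are in the mask; neighbours outside the grid count as background, so the
#' mask also shrinks at the array border). Used to trim region masks against
#' partial-volume contamination before regridding.
#'
#' @param mask logical 3D array.
#' @param iterations nonnegative integer.
#' @return Logical 3D array, a subset of `mask`.
#' @export
erodeMask <- function(mask, iterations = 3L) {
  stopifnot(length(dim(mask)) == 3L, iterations >= 0)
  mask <- array(as.logical(mask), dim = dim(mask))
  for (i in seq_len(iterations)) {
    m <- mask
    for (ax in 1:3) {
      m <- m & .shift3d(mask, ax, 1L) & .shift3d(mask, ax, -1L)
    }
    mask <- m
  }
  if (iterations > 0 && !any(mask))
    warning("mask fully eroded; returning an empty mask")
  mask
}

# Global cube index (1-based, lexicographic with dim 1 fastest) per voxel.
.cubeIndexOf <- function(ai, dims, factor) {
  nc <- ceiling(dims / factor)
  ci <- (ai[, 1] - 1L) %/% factor
  cj <- (ai[, 2] - 1L) %/% factor
  ck <- (ai[, 3] - 1L) %/% factor
  as.integer(ci + nc[1] * (cj + nc[2] * ck) + 1L)
}

#' Partition a masked grid into cubic blocks and average volumes per block
#'
#' Tiles the grid from array index (1,1,1) into `factor`^3 cubes. For every
#' cube, the mean of each supplied volume over the cube's in-mask voxels is
#' computed; cubes whose in-mask voxel fraction (relative to a full
#' `factor`^3 cube) is below `minFill` are dropped. Retained blocks are
#' labelled 1..K in lexicographic cube order.
#'
#' @param volumes named list of numeric 3D arrays (metric and/or count maps).
#' @param mask logical 3D array (nonempty).
#' @param factor block edge length in voxels (>= 1, not larger than every
#'   grid dimension).
#' @param minFill minimum in-mask voxel fraction for a block to be retained
#'   (default 0.5).
#' @return `list(partition = BlockPartition, table = data.frame)` where the
#'   table has columns `block_id`, `cube_index`, then one mean per volume.
#' @export
blockPartitionAndMeans <- function(volumes, mask, factor, minFill = 0.5) {
  dims <- dim(mask)
  factor <- as.integer(factor)
  stopifnot(length(volumes) >= 1, !is.null(names(volumes)), factor >= 1)
  if (all(factor > dims))
    stop("block factor ", factor, " exceeds every grid dimension")
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  ai <- arrayInd(idx, dims)
  cube <- .cubeIndexOf(ai, dims, factor)
  counts <- table(cube)
  keep <- as.integer(names(counts))[as.vector(counts) / factor^3 >= minFill]
  keep <- sort(keep)
  if (!length(keep))
    return(list(
      partition = new("BlockPartition",
                      labels = array(0L, dim = dims), factor = factor,
                      blockIds = integer(0), cubeIndex = integer(0)),
      table = data.frame(block_id = integer(0), cube_index = integer(0))))
  inKeep <- cube %in% keep
  lab <- match(cube[inKeep], keep)
  labels <- array(0L, dim = dims)
  labels[idx[inKeep]] <- lab
  tab <- data.frame(block_id = seq_along(keep), cube_index = keep)
  n <- as.vector(rowsum(rep(1, sum(inKeep)), lab))
  for (nm in names(volumes)) {
    v <- volumes[[nm]][idx[inKeep]]
    tab[[nm]] <- as.vector(rowsum(v, lab)) / n
  }
  list(partition = new("BlockPartition", labels = labels, factor = factor,
                       blockIds = seq_along(keep), cubeIndex = as.integer(keep)),
       table = tab)
}

#' Inter-subject variance score of a set of block tables
#'
#' For each metric column, computes the variance across subjects within
#' each block (sample variance, denominator n-1), takes the median over
#' blocks (block counts differ between factors), and finally averages over
#' the metric columns. Smaller is better: the criterion rewards block sizes
#' large enough to absorb residual misalignment between subjects.
#'
#' @param tables list of per-subject block tables (same block ids, from
#'   [blockPartitionAndMeans()]).
#' @param metricCols columns to score (default: the diffusion metrics
#'   present in the tables).
#' @return Nonnegative scalar.
#' @export
intersubjectVarianceScore <- function(tables, metricCols = NULL) {
  stopifnot(length(tables) >= 2)
  ids <- lapply(tables, `[[`, "block_id")
  if (length(unique(ids)) != 1L)
    stop("block ids are mismatched across subjects")
  if (is.null(metricCols))
    metricCols <- intersect(.METRICS, colnames(tables[[1]]))
  stopifnot(length(metricCols) >= 1)
  perMetric <- vapply(metricCols, function(mc) {
    M <- vapply(tables, `[[`, numeric(nrow(tables[[1]])), mc)
    M <- matrix(M, nrow = nrow(tables[[1]]))
    mu <- rowMeans(M)
    v <- rowSums((M - mu)^2) / (ncol(M) - 1)
    stats::median(v)
  }, numeric(1))
  mean(perMetric)
}

# Per-subject block tables of a cohort over an arbitrary mask.
# counts = "reference" uses the shared atlas counts, "subject" the
# subject's own (jittered) count fields, "none" omits count columns.
.cohortTables <- function(cohort, mask, factor, minFill = 0.5,
                          counts = c("reference", "subject", "none")) {
  counts <- match.arg(counts)
  n <- nSubjects(cohort)
  tables <- vector("list", n)
  partition <- NULL
  for (s in seq_len(n)) {
    vols <- cohort@metricSets[[s]]@metrics
    if (counts == "reference")
      vols <- c(vols, cohort@referenceCounts@counts)
    else if (counts == "subject")
      vols <- c(vols, cohort@countSets[[s]]@counts)
    bm <- blockPartitionAndMeans(vols, mask, factor, minFill)
    tables[[s]] <- bm$table
    if (is.null(partition)) partition <- bm$partition
  }
  list(tables = tables, partition = partition)
}

#' Select the block factor minimizing inter-subject variance
#'
#' Evaluates [intersubjectVarianceScore()] on the cohort's metric block
#' tables at every candidate factor and returns the argmin; ties are broken
#' toward the smaller factor. A candidate that retains zero blocks is
#' scored +Inf with a warning.
#'
#' @param cohort a [Cohort-class].
#' @param mask logical 3D array; default is the union of all region masks
#'   eroded by `erodeIters` passes.
#' @param candidates integer vector of factors to try (default 10..50 in
#'   steps of 5, the coarse-search range appropriate for real acquisitions;
#'   small phantoms should pass smaller candidates).
#' @param erodeIters erosion passes for the default mask.
#' @param minFill passed to [blockPartitionAndMeans()].
#' @return `list(factor = best, scores = named numeric per candidate)`.
#' @export
optimizeBlockFactor <- function(cohort, mask = NULL,
                                candidates = seq(10L, 50L, by = 5L),
                                erodeIters = 3L, minFill = 0.5) {
  stopifnot(length(candidates) >= 1)
  if (is.null(mask))
    mask <- erodeMask(atlasLabels(cohort@atlas) > 0, erodeIters)
  candidates <- sort(as.integer(candidates))
  scores <- vapply(candidates, function(f) {
    ct <- .cohortTables(cohort, mask, f, minFill, counts = "none")
    if (nrow(ct$tables[[1]]) == 0L) {
      warning("factor ", f, " retains zero blocks; scored as +Inf")
      return(Inf)
    }
    intersubjectVarianceScore(ct$tables)
  }, numeric(1))
  names(scores) <- candidates
  list(factor = candidates[which.min(scores)], scores = scores)
}
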