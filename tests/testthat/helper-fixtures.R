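# Shared fixtures, built lazily and cached for the duration of a test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# Two disjoint 26^3-ish regions on a 56 x 30 x 30 grid.
twoRegionAtlas <- function() fixture("twoRegionAtlas", function() {
  makeAtlas(c(56, 30, 30), list(
    A = cuboidRegion(c(2, 4, 4), c(27, 27, 27)),
    B = cuboidRegion(c(30, 4, 4), c(55, 27, 27))))
})

# Default-condition cohort (region-specific relationships, noise, jitter).
strongCohort <- function() fixture("strongCohort", function() {
  makeCohort(twoRegionAtlas(), cohortSpec(twoRegionAtlas(), seed = 7L))
})

# Full-null cohort: no metric/count relationships at all.
nullCohort <- function() fixture("nullCohort", function() {
  atlas <- twoRegionAtlas()
  makeCohort(atlas, cohortSpec(
    atlas, relationships = nullRelationships(atlas), seed = 3L))
})

# Fast predictor settings used throughout the suite: singleton grid and a
# short linear autoencoder keep one LOO evaluation at a couple of seconds.
fastGrid <- function(mtry = 2L)
  data.frame(num.trees = 100L, mtry = mtry, min.node.size = 5L)
fastCompressor <- function(latentDim = 3L)
  compressorConfig(latentDim = latentDim, epochs = 150L)

# Independent brute-force erosion oracle (6-connectivity, zero padding).
bruteErode <- function(mask, iterations) {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!mask[i, j, k]) next
      nb <- TRUE
      for (dd in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + dd[1]; jj <- j + dd[2]; kk <- k + dd[3]
        if (ii < 1 || jj < 1 || kk < 1 ||
            ii > d[1] || jj > d[2] || kk > d[3] || !mask[ii, jj, kk]) {
          nb <- FALSE; break
        }
      }
      out[i, j, k] <- nb
    }
    mask <- out
  }
  mask
}

# Independent step-down Sidak oracle: explicit loop over the sorted order.
bruteHolmSidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, min(a, 1))
    adj[o[i]] <- running
  }
  adj
}
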