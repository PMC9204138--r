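# Mask erosion, block partitioning/averaging and block-factor selection.

test_that("erosion matches a brute-force oracle and handles edge cases", {
  # solid 9^3 cube inside an 11^3 grid -> 3 passes leave the 3^3 interior
  m <- array(FALSE, c(11, 11, 11)); m[2:10, 2:10, 2:10] <- TRUE
  e3 <- erodeMask(m, 3)
  expect_equal(sum(e3), 27)
  expect_true(all(e3[5:7, 5:7, 5:7]))
  expect_equal(e3, bruteErode(m, 3))
  # iterations = 0 is the identity
  expect_identical(erodeMask(m, 0), m)
  # 5^3 cube fully erodes in 3 passes
  m5 <- array(FALSE, c(9, 9, 9)); m5[3:7, 3:7, 3:7] <- TRUE
  expect_warning(e5 <- erodeMask(m5, 3), "fully eroded")
  expect_false(any(e5))
  # irregular mask against the oracle (mask shrinks at the array border too)
  set.seed(11)
  mr <- array(runif(12^3) > 0.35, c(12, 12, 12))
  expect_equal(suppressWarnings(erodeMask(mr, 2)), bruteErode(mr, 2))
})

test_that("block means follow the arithmetic of the in-mask voxels", {
  dims <- c(4, 4, 4)
  full <- array(TRUE, dims)
  vol <- array(seq_len(64), dims)
  # factor 1, full mask: table reproduces the voxels in lexicographic order
  bm1 <- blockPartitionAndMeans(list(v = vol), full, 1)
  expect_equal(bm1$table$v, as.vector(vol))
  expect_equal(nrow(bm1$table), 64)
  # a 2x2x2 volume of 1..8 collapses to one block of mean 4.5
  v2 <- array(1:8, c(2, 2, 2))
  bm2 <- blockPartitionAndMeans(list(v = v2), array(TRUE, c(2, 2, 2)), 2)
  expect_equal(nrow(bm2$table), 1)
  expect_equal(bm2$table$v, 4.5)
  # constant volumes give constant means at any factor
  bmC <- blockPartitionAndMeans(list(v = array(7, dims)), full, 2)
  expect_true(all(bmC$table$v == 7))
  expect_equal(nrow(bmC$table), 8)
  # every mean lies within the range of the voxels it covers
  set.seed(2)
  vr <- array(rnorm(64), dims)
  bmR <- blockPartitionAndMeans(list(v = vr), full, 2)
  for (b in bmR$table$block_id) {
    vox <- vr[bmR$partition@labels == b]
    expect_gte(bmR$table$v[b], min(vox))
    expect_lte(bmR$table$v[b], max(vox))
  }
  expect_error(blockPartitionAndMeans(list(v = vol), full, 5), "exceeds")
})

test_that("partial blocks honour the minFill threshold", {
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  mask[1, , ] <- FALSE   # first-x slab removed: the 4 low-x blocks half-filled
  vol <- array(1, dims)
  keep <- blockPartitionAndMeans(list(v = vol), mask, 2, minFill = 0.5)
  expect_equal(nrow(keep$table), 8)
  drop <- blockPartitionAndMeans(list(v = vol), mask, 2, minFill = 0.6)
  expect_equal(nrow(drop$table), 4)
})

test_that("block averaging is idempotent on block-constant volumes", {
  dims <- c(6, 6, 6)
  full <- array(TRUE, dims)
  set.seed(4)
  v <- array(rnorm(prod(dims)), dims)
  bm <- blockPartitionAndMeans(list(v = v), full, 3)
  vc <- v
  for (b in bm$table$block_id) vc[bm$partition@labels == b] <- bm$table$v[b]
  bm2 <- blockPartitionAndMeans(list(v = vc), full, 3)
  expect_equal(bm2$table, bm$table)
})

test_that("inter-subject variance score matches hand-computed values", {
  mkTab <- function(vals) {
    tab <- data.frame(block_id = 1L)
    for (m in c("AD", "ADC", "FA", "RD", "NDI", "ODI")) tab[[m]] <- vals[[m]]
    tab
  }
  base <- c(AD = 1, ADC = 2, FA = 3, RD = 4, NDI = 5, ODI = 6)
  delta <- 0.3
  shifted <- base; shifted[["FA"]] <- base[["FA"]] + delta
  # identical tables -> 0
  expect_equal(intersubjectVarianceScore(list(mkTab(base), mkTab(base))), 0)
  # one metric differing by delta in one of two subjects:
  # var = delta^2 / 2 (ddof 1), median over the single block, mean over 6
  expect_equal(intersubjectVarianceScore(list(mkTab(base), mkTab(shifted))),
               (delta^2 / 2) / 6)
  # shift invariance: adding a constant to every subject leaves the score
  plus <- lapply(list(base, shifted), function(b) mkTab(b + 10))
  expect_equal(intersubjectVarianceScore(plus),
               (delta^2 / 2) / 6)
  # invariant under a common permutation of subjects
  expect_equal(intersubjectVarianceScore(list(mkTab(shifted), mkTab(base))),
               intersubjectVarianceScore(list(mkTab(base), mkTab(shifted))))
  bad <- mkTab(base); bad$block_id <- 2L
  expect_error(intersubjectVarianceScore(list(mkTab(base), bad)), "mismatched")
})

test_that("optimizeBlockFactor returns the argmin of an independent sweep", {
  coh <- strongCohort()
  mask <- erodeMask(atlasLabels(coh@atlas) > 0, 3)
  cand <- c(3L, 4L, 5L, 6L)
  opt <- optimizeBlockFactor(coh, mask, candidates = cand)
  # oracle: recompute the criterion per factor with independent code
  oracle <- sapply(cand, function(f) {
    tabs <- lapply(seq_len(nSubjects(coh)), function(s)
      blockPartitionAndMeans(coh@metricSets[[s]]@metrics, mask, f)$table)
    perMetric <- sapply(c("AD", "ADC", "FA", "RD", "NDI", "ODI"), function(m) {
      M <- sapply(tabs, `[[`, m)
      median(apply(M, 1, var))
    })
    mean(perMetric)
  })
  expect_equal(unname(opt$scores), oracle)
  expect_equal(opt$factor, cand[which.min(oracle)])
  # singleton candidate list is returned unchanged
  expect_equal(optimizeBlockFactor(coh, mask, candidates = 6L)$factor, 6L)
})

test_that("factor ties break toward the smaller candidate and empty
           candidates score +Inf", {
  atlas <- makeAtlas(c(12, 12, 12), list(R = cuboidRegion(c(1, 1, 1), c(12, 12, 12))))
  spec <- cohortSpec(atlas, nSubjects = 2L, relationships = nullRelationships(atlas),
                     noiseSd = setNames(rep(0, 6), c("AD", "ADC", "FA", "RD", "NDI", "ODI")),
                     jitterSd = 0, seed = 1L)
  coh <- makeCohort(atlas, spec)   # identical noiseless subjects: all scores 0
  mask <- array(TRUE, c(12, 12, 12))
  opt <- optimizeBlockFactor(coh, mask, candidates = c(6L, 3L, 4L))
  expect_equal(opt$factor, 3L)
  expect_true(all(opt$scores == 0))
  # a thin slab fills < 50% of any 11^3 cube -> zero retained blocks
  slab <- array(FALSE, c(12, 12, 12)); slab[, , 1:2] <- TRUE
  expect_warning(
    opt2 <- optimizeBlockFactor(coh, slab, candidates = c(3L, 11L)),
    "zero blocks")
  expect_equal(unname(opt2$scores[["11"]]), Inf)
  expect_equal(opt2$factor, 3L)
})
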