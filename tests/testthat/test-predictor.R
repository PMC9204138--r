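# Tree-ensemble regression, LOO evaluation, bootstrap and transfer checks.

test_that("grid search recovers a pure-signal target and a singleton grid
           is returned unchanged", {
  set.seed(1)
  Z <- matrix(rnorm(150 * 3), 150, 3)
  y <- Z[, 2]
  fit <- fitRegressor(Z, y, seed = 5L)
  expect_true(fit$params$num.trees %in% c(250L, 1000L))
  # held-out check on fresh rows drawn from the same construction
  Zte <- matrix(rnorm(60 * 3), 60, 3)
  # oracle: a 1-nearest-neighbour regressor succeeds on this construction,
  # so the tree ensemble must too
  nn <- sapply(seq_len(60), function(i) {
    j <- which.min(colSums((t(Z) - Zte[i, ])^2)); y[j]
  })
  expect_gt(cor(nn, Zte[, 2]), 0.9)
  pr <- dwicell:::.predictTrees(fit$model, Zte)
  expect_gt(cor(pr, Zte[, 2]), 0.9)
  g1 <- data.frame(num.trees = 42L, mtry = 1L, min.node.size = 3L)
  fit1 <- fitRegressor(Z, y, grid = g1, seed = 5L)
  expect_equal(fit1$params, g1)
  expect_error(fitRegressor(Z, rep(1, 150)), "constant target")
})

test_that("permuted targets give held-out R near zero", {
  set.seed(2)
  meanR <- mean(sapply(1:50, function(i) {
    Z <- matrix(rnorm(60 * 3), 60, 3)
    y <- sample(rnorm(60))
    tr <- 1:40
    fit <- fitRegressor(Z[tr, ], y[tr],
                        grid = data.frame(num.trees = 100L, mtry = 2L,
                                          min.node.size = 5L), seed = i)
    cor(dwicell:::.predictTrees(fit$model, Z[-tr, ]), y[-tr])
  }))
  expect_lt(abs(meanR), 0.1)
})

test_that("LOO evaluation recovers strong phantom relationships and books
           folds correctly", {
  coh <- strongCohort()
  pr <- looEvaluate(coh, "A", "Glia", factor = 4, grid = fastGrid(),
                    compressor = fastCompressor())
  expect_gte(pr@R, 0.95)
  expect_lt(pr@p, 1e-6)
  # reported R always equals the recomputed correlation of stored columns
  expect_equal(pr@R, cor(pr@reference, pr@predicted))
  expect_equal(ncol(pr@bySubject), nSubjects(coh))
  expect_false(anyNA(pr@bySubject))
  expect_equal(length(pr@blockId), length(pr@reference))
  # line coefficients match lm on the stored columns
  cf <- coef(lm(pr@predicted ~ pr@reference))
  expect_equal(pr@slope, unname(cf[2]))
  expect_equal(pr@intercept, unname(cf[1]))
})

test_that("a 2-subject cohort yields exactly 2 folds covering each block once", {
  atlas <- twoRegionAtlas()
  coh <- makeCohort(atlas, cohortSpec(atlas, nSubjects = 2L, seed = 13L))
  pr <- looEvaluate(coh, "A", "Glia", factor = 4, grid = fastGrid(),
                    compressor = fastCompressor())
  expect_equal(ncol(pr@bySubject), 2L)
  # every block predicted exactly once per fold column
  expect_true(all(is.finite(pr@bySubject)))
  expect_equal(pr@predicted, rowMeans(pr@bySubject))
})

test_that("null phantoms give |R| < 0.2 and LOO fidelity decays with noise", {
  cohN <- nullCohort()
  prN <- looEvaluate(cohN, "A", "Glia", factor = 4, grid = fastGrid(),
                     compressor = fastCompressor())
  expect_lt(abs(prN@R), 0.2)
  # noise ladder: median R nonincreasing as metric noise grows
  atlas <- twoRegionAtlas()
  base <- c(AD = 0.04, ADC = 0.03, FA = 0.02, RD = 0.03, NDI = 0.02, ODI = 0.02)
  Rs <- sapply(c(0, 1, 4, 16), function(k) {
    coh <- makeCohort(atlas, cohortSpec(atlas, noiseSd = base * k, seed = 31L))
    looEvaluate(coh, "A", "Glia", factor = 4, grid = fastGrid(),
                compressor = fastCompressor())@R
  })
  expect_true(all(diff(Rs) <= 0.05))  # nonincreasing up to fit jitter
  expect_gt(Rs[1], Rs[4])
})

test_that("region-specific models beat a pooled model under opposite signs", {
  atlas <- twoRegionAtlas()
  # same tissue character both sides, opposite relationship signs
  bl <- list(A = c(Neurons = 200, Oligodendrocytes = 40, Astrocytes = 50,
                   Microglia = 30),
             B = c(Neurons = 200, Oligodendrocytes = 40, Astrocytes = 50,
                   Microglia = 30))
  perRegion <- matrix(NA_real_, 10, 2)
  pooled <- numeric(10)
  for (i in 1:10) {
    coh <- makeCohort(atlas, cohortSpec(atlas, baselines = bl,
                                        seed = 100L + i))
    perRegion[i, 1] <- looEvaluate(coh, "A", "Glia", 4, grid = fastGrid(),
                                   compressor = fastCompressor(), seed = i)@R
    perRegion[i, 2] <- looEvaluate(coh, "B", "Glia", 4, grid = fastGrid(),
                                   compressor = fastCompressor(), seed = i)@R
    pooled[i] <- looEvaluate(coh, c(1, 2), "Glia", 4, grid = fastGrid(),
                             compressor = fastCompressor(), seed = i)@R
  }
  expect_gte(median(perRegion[, 1]), 0.4)
  expect_gte(median(perRegion[, 2]), 0.4)
  expect_lt(median(pooled), median(perRegion[, 1]))
  expect_lt(median(pooled), median(perRegion[, 2]))
})

test_that("bootstrap distributions have the configured length and are seeded", {
  coh <- strongCohort()
  bs <- bootstrapPerformance(coh, "A", "Glia", factor = 4, nIter = 5,
                             grid = fastGrid(), compressor = fastCompressor(),
                             seed = 9L)
  expect_equal(nrow(bs), 5L)
  expect_true(all(abs(bs$R) <= 1))
  bs2 <- bootstrapPerformance(coh, "A", "Glia", factor = 4, nIter = 5,
                              grid = fastGrid(), compressor = fastCompressor(),
                              seed = 9L)
  expect_identical(bs, bs2)
  # n_iter = 1 reproduces the single subsampled pass bit-exactly
  one <- bootstrapPerformance(coh, "A", "Glia", factor = 4, nIter = 1,
                              grid = fastGrid(), compressor = fastCompressor(),
                              seed = 9L)
  expect_identical(one, bs[1, ])
})

test_that("strong-phantom bootstrap R dominates the null phantom's", {
  nIt <- 30
  bsS <- bootstrapPerformance(strongCohort(), "A", "Glia", factor = 4,
                              nIter = nIt, grid = fastGrid(),
                              compressor = fastCompressor(), seed = 2L)
  bsN <- bootstrapPerformance(nullCohort(), "A", "Glia", factor = 4,
                              nIter = nIt, grid = fastGrid(),
                              compressor = fastCompressor(), seed = 2L)
  q90 <- quantile(bsN$R, 0.9)
  expect_gte(mean(bsS$R > q90), 0.9)
})

test_that("70% subsamplings give slopes consistent with the full-data fit", {
  # the subsampling must not drive the fitted relationship: the slope
  # distribution concentrates tightly around the full-data slope
  coh <- strongCohort()
  full <- looEvaluate(coh, "A", "Glia", factor = 4, grid = fastGrid(),
                      compressor = fastCompressor(), seed = 3L)
  bs <- bootstrapPerformance(coh, "A", "Glia", factor = 4,
                             subsampleFrac = 0.7, nIter = 100,
                             grid = fastGrid(), compressor = fastCompressor(),
                             seed = 3L)
  iqr <- quantile(bs$slope, c(0.25, 0.75))
  expect_lt(abs(median(bs$slope) - full@slope) / abs(full@slope), 0.1)
  expect_true(all(abs(iqr - full@slope) / abs(full@slope) < 0.1))
  expect_true(all(bs$slope > 0))
})

test_that("hemisphere transfer works on symmetric phantoms and fails across
           opposite-sign regions", {
  atlas <- makeAtlas(c(56, 28, 28), list(
    M = cuboidRegion(c(3, 3, 3), c(26, 26, 26), mirror = TRUE)))
  coh <- makeCohort(atlas, cohortSpec(atlas, seed = 17L))
  xfer <- transferEvaluate(coh, train = list(region = "M", hemisphere = "left"),
                           test = list(region = "M", hemisphere = "right"),
                           cellType = "Glia", factor = 4, grid = fastGrid(),
                           compressor = fastCompressor())
  loo <- looEvaluate(coh, "M", "Glia", factor = 4, grid = fastGrid(),
                     compressor = fastCompressor())
  expect_gt(xfer$R, 0.4)
  expect_lt(xfer$p, 0.05)
  expect_lt(abs(xfer$R - loo@R), 0.2)
  # cross-region transfer under opposite signs performs at or below chance
  coh2 <- strongCohort()
  x2 <- transferEvaluate(coh2, train = list(region = "A"),
                         test = list(region = "B"),
                         cellType = "Glia", factor = 4, grid = fastGrid(),
                         compressor = fastCompressor())
  expect_true(x2$R <= 0 || x2$p > 0.2)
  # leakage guard: target = source
  expect_error(
    transferEvaluate(coh2, train = list(region = "A"),
                     test = list(region = "A"), cellType = "Glia",
                     factor = 4, grid = fastGrid(),
                     compressor = fastCompressor()),
    "leakage")
})
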