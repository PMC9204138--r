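# Phantom cohort generator: atlas construction, count hierarchy, configured
# relationships, determinism, noise calibration, and the DWI signal model.

test_that("makeAtlas builds disjoint labelled cuboids and rejects overlap", {
  atlas <- makeAtlas(c(60, 60, 60), list(
    R1 = cuboidRegion(c(1, 1, 1), c(20, 20, 20)),
    R2 = cuboidRegion(c(31, 31, 31), c(50, 50, 50))))
  expect_setequal(unique(as.vector(atlasLabels(atlas))), c(0L, 1L, 2L))
  expect_equal(sum(atlasLabels(atlas) == 1L), 8000L)
  expect_equal(sum(atlasLabels(atlas) == 2L), 8000L)
  expect_equal(unname(regionNames(atlas)), c("R1", "R2"))
  expect_error(
    makeAtlas(c(40, 40, 40), list(
      P = cuboidRegion(c(1, 1, 1), c(20, 20, 20)),
      Q = cuboidRegion(c(20, 20, 20), c(30, 30, 30)))),
    "'P' and 'Q' overlap")
})

test_that("mirrored layouts put equal region volume in both hemispheres", {
  atlas <- makeAtlas(c(40, 20, 20), list(
    H = cuboidRegion(c(3, 3, 3), c(14, 14, 14), mirror = TRUE)))
  lab <- atlasLabels(atlas)
  left <- lab[1:20, , ]; right <- lab[21:40, , ]
  expect_equal(sum(left == 1L), sum(right == 1L))
  expect_gt(sum(left == 1L), 0)
  # mirrored voxel-for-voxel
  expect_equal(left, right[dim(right)[1]:1, , ])
})

test_that("generated cohorts satisfy the cell-class hierarchy exactly", {
  coh <- strongCohort()
  for (s in c(1L, nSubjects(coh))) {
    cts <- coh@countSets[[s]]@counts
    expect_equal(cts$Glia,
                 cts$Oligodendrocytes + cts$Astrocytes + cts$Microglia)
    expect_equal(cts$Cells, cts$Neurons + cts$Glia)
    expect_true(all(cts$Cells >= 0))
  }
  ref <- coh@referenceCounts@counts
  expect_equal(ref$Cells, ref$Neurons + ref$Glia)
})

test_that("noiseless, jitter-free relationships give r = +/-1 by sign", {
  atlas <- twoRegionAtlas()
  rel <- defaultRelationships(atlas)   # sign +1 in A, -1 in B
  spec <- cohortSpec(atlas, nSubjects = 2L, relationships = rel,
                     noiseSd = setNames(rep(0, 6), c("AD", "ADC", "FA", "RD", "NDI", "ODI")),
                     jitterSd = 0, seed = 5L)
  coh <- makeCohort(atlas, spec)
  for (s in 1:2) {
    fa <- metricVolume(coh, s, "FA")
    glia <- countVolume(coh, s, "Glia")
    inA <- atlasLabels(atlas) == 1L
    inB <- atlasLabels(atlas) == 2L
    expect_equal(cor(fa[inA], glia[inA]), 1)
    expect_equal(cor(fa[inB], glia[inB]), -1)
  }
})

test_that("generation is a pure function of the seed", {
  atlas <- twoRegionAtlas()
  c1 <- makeCohort(atlas, cohortSpec(atlas, nSubjects = 2L, seed = 42L))
  c2 <- makeCohort(atlas, cohortSpec(atlas, nSubjects = 2L, seed = 42L))
  expect_identical(c1@metricSets[[2]]@metrics, c2@metricSets[[2]]@metrics)
  expect_identical(c1@countSets[[1]]@counts, c2@countSets[[1]]@counts)
  c3 <- makeCohort(atlas, cohortSpec(atlas, nSubjects = 2L, seed = 43L))
  expect_false(identical(c1@metricSets[[1]]@metrics$AD,
                         c3@metricSets[[1]]@metrics$AD))
})

test_that("relationships referencing unknown names are rejected", {
  atlas <- twoRegionAtlas()
  rel <- nullRelationships(atlas)
  rel$A$FA$slopes <- c(Nonsense = 1)
  expect_error(makeCohort(atlas, cohortSpec(atlas, relationships = rel)),
               "unknown cell type")
  rel <- nullRelationships(atlas)
  names(rel$A)[1] <- "QQ"
  expect_error(makeCohort(atlas, cohortSpec(atlas, relationships = rel)),
               "unknown metric")
  expect_error(makeCohort(atlas, cohortSpec(atlas, relationships = list(A = rel$A))),
               "missing for region")
})

test_that("empirical metric noise sd matches the configured level", {
  atlas <- makeAtlas(c(28, 28, 28),
                     list(R = cuboidRegion(c(3, 3, 3), c(24, 24, 24))))
  spec <- cohortSpec(atlas, nSubjects = 2L, jitterSd = 0, seed = 9L)
  coh <- makeCohort(atlas, spec)
  inR <- atlasLabels(atlas) == 1L
  expect_gte(sum(inR), 1e4)
  # residual after removing the affine count term is exactly the noise
  fa <- metricVolume(coh, 1, "FA")
  glia <- countVolume(coh, 1, "Glia")
  rel <- spec@relationships$R$FA
  resid <- fa[inR] - (rel$intercept + rel$slopes[["Glia"]] * glia[inR])
  expect_lt(abs(sd(resid) - spec@noiseSd[["FA"]]) / spec@noiseSd[["FA"]], 0.1)
})

test_that("the DWI signal follows the closed-form tensor model", {
  g <- c(1, 0, 0)
  sch <- gradientScheme(c(0, 1000, 3000), cbind(c(0, 0, 0), g, g))
  d <- 0.8
  S <- simulateDWI(diag(rep(d, 3)), sch, s0 = 200)
  expect_equal(as.vector(S), 200 * exp(-c(0, 1, 3) * d), tolerance = 1e-12)
  # anisotropic closed form: b = 1000 s/mm^2 along x, Dxx = 1.5
  D <- diag(c(1.5, 0.3, 0.3))
  S2 <- simulateDWI(D, sch, s0 = 1)
  expect_equal(S2[1, 2], exp(-1.5), tolerance = 1e-12)
  expect_equal(S2[1, 1], 1)   # b0 independent of D
  expect_error(simulateDWI(matrix(c(1, 0.2, 0, 0, 1, 0, 0, 0, 1), 3, 3), sch),
               "symmetric")
})

test_that("Rician noise is seeded and vanishes at noiseSd = 0", {
  sch <- defaultGradientScheme()
  D <- diag(c(1.2, 0.5, 0.5))
  a <- simulateDWI(D, sch, s0 = 100, noiseSd = 2, seed = 4L)
  b <- simulateDWI(D, sch, s0 = 100, noiseSd = 2, seed = 4L)
  c3 <- simulateDWI(D, sch, s0 = 100, noiseSd = 2, seed = 5L)
  expect_identical(a, b)
  expect_false(identical(a, c3))
  expect_true(all(a > 0))
})

test_that("gradient schemes round-trip through bval/bvec files", {
  sch <- defaultGradientScheme()
  expect_equal(length(sch@bvals), 74L)
  expect_equal(sum(sch@bvals == 1000), 20L)
  expect_equal(sum(sch@bvals == 3000), 52L)
  pre <- file.path(withr::local_tempdir(), "grad")
  writeGradientScheme(sch, pre)
  back <- readGradientScheme(paste0(pre, ".bval"), paste0(pre, ".bvec"))
  expect_equal(back@bvals, sch@bvals)
  expect_equal(back@bvecs, sch@bvecs, tolerance = 1e-8)
})
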