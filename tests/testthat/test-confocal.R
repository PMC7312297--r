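# Lateral smoothing, apical-contour detection, mask construction,
# localization scoring and cell-height estimation.

test_that("lateral smoothing leaves constant slices unchanged and mixes nothing across z", {
  x <- array(0, c(12, 12, 3))
  x[, , 1] <- 4; x[, , 2] <- 7; x[, , 3] <- 1
  sm <- smoothLateral(x, width = 10)
  expect_equal(sm, x)
})

test_that("smoothing matches a direct convolution oracle with unit kernel mass", {
  set.seed(5)
  m <- matrix(runif(15 * 13, 0, 255), 15, 13)
  g <- EpiBarrier:::.gaussKernel1d(6)
  expect_equal(sum(g), 1)
  sm <- smoothLateral(array(m, c(15, 13, 1)), width = 6)[, , 1]
  expect_equal(sm, oracleConvolve2d(m, g), tolerance = 1e-12)
  expect_error(smoothLateral(array(0, c(4, 4, 2)), width = 10), "width")
})

test_that("contour detection matches a per-column brute-force scan", {
  # worked column: (0, 0, 10, 10) crosses 30% of max at the third slice
  a <- array(0, c(1, 1, 4)); a[1, 1, ] <- c(0, 0, 10, 10)
  expect_equal(detectApicalContour(a, backgroundFloor = 0)[1, 1], 3L)
  set.seed(11)
  x <- array(runif(6 * 6 * 12, 0, 100), c(6, 6, 12))
  cm <- detectApicalContour(x, thresholdFrac = 0.3, backgroundFloor = 0)
  for (i in 1:6) for (j in 1:6)
    expect_equal(cm[i, j], oracleFirstCrossing(x[i, j, ], 0.3))
})

test_that("all-zero columns are background and empty fields are an error", {
  a <- array(0, c(3, 3, 8))
  a[1:2, , 5:8] <- 50                       # one background row of columns
  cm <- detectApicalContour(a)
  expect_true(all(is.na(cm[3, ])))
  expect_true(all(cm[1:2, ] == 5L))
  expect_error(detectApicalContour(array(0, c(3, 3, 8))), "background")
  expect_error(detectApicalContour(a, thresholdFrac = 1.2), "thresholdFrac")
})

test_that("mask index arithmetic follows the stripe convention", {
  # contour at z = 6 (1-based), stripe 12, nz = 40:
  # membrane z 6..17, cytoplasm z 18..40
  cm <- matrix(6L, 3, 3)
  m <- buildMasks(cm, stripeWidth = 12, dim = c(3, 3, 40))
  zmem <- which(membraneMask(m)[1, 1, ])
  zcyt <- which(cytoplasmMask(m)[1, 1, ])
  expect_equal(zmem, 6:17)
  expect_equal(zcyt, 18:40)
  # contour at the basal slice: one membrane voxel, empty cytoplasm, flagged
  deep <- buildMasks(matrix(40L, 2, 2), stripeWidth = 12, dim = c(2, 2, 40))
  expect_equal(which(membraneMask(deep)[1, 1, ]), 40L)
  expect_equal(sum(cytoplasmMask(deep)), 0L)
  expect_true(all(degenerateColumns(deep)))
})

test_that("membrane, cytoplasm, above-contour and background partition the grid", {
  for (surf in c("flat", "step", "smooth")) {
    sim <- simulateConfocalStack(nx = 20, ny = 20, nz = 30, surface = surf,
                                 seed = 13)
    sm <- smoothLateral(membraneChannel(sim$stack), width = 10)
    cm <- detectApicalContour(sm)
    msk <- buildMasks(cm, 12, dim = c(20, 20, 30))
    mem <- membraneMask(msk); cyt <- cytoplasmMask(msk)
    c3 <- array(rep(contourMap(msk), 30), dim = c(20, 20, 30))
    z3 <- array(rep(1:30, each = 400), dim = c(20, 20, 30))
    above <- !is.na(c3) & z3 < c3
    bg3 <- array(backgroundColumns(msk), dim = c(20, 20, 30))
    expect_true(all(mem + cyt + above + bg3 == 1))  # disjoint and exhaustive
  }
})

test_that("localization ratio recovers the ground truth and scales invariantly", {
  sim <- simulateConfocalStack(nx = 16, ny = 16, nz = 40, enrichment = 2,
                               noiseSd = 0, seed = 7)
  sc <- measureLocalization(sim$stack, sim$masks)
  expect_equal(sc$ratio, 2.0)
  expect_equal(sc$membraneVoxels, sum(membraneMask(sim$masks)))
  # uniform target channel gives ratio exactly 1
  uni <- array(80, dim = c(16, 16, 40))
  expect_equal(measureLocalization(uni, sim$masks)$ratio, 1.0)
  # invariant to uniform intensity scaling
  sc5 <- measureLocalization(targetChannel(sim$stack) * 5, sim$masks)
  expect_equal(sc5$ratio, sc$ratio)
  # empty cytoplasm everywhere is a hard error
  deep <- buildMasks(matrix(40L, 16, 16), 12, c(16, 16, 40))
  expect_error(measureLocalization(uni, deep), "cytoplasm mask is empty")
})

test_that("cell height averages (basal - contour) * axial spacing", {
  expect_equal(estimateCellHeight(matrix(6L, 4, 4), zBasal = 46, axial = 0.2),
               8.0)
  expect_equal(estimateCellHeight(matrix(46L, 2, 2), zBasal = 46, axial = 0.2),
               0)
  expect_error(estimateCellHeight(matrix(10L, 2, 2), zBasal = 5, axial = 0.2),
               "basal")
  # synthetic stack: recovered mean height within one axial voxel
  sim <- simulateConfocalStack(nx = 32, ny = 32, nz = 40, surfaceDepth = 2,
                               surfaceAmplitude = 1, seed = 21)
  sm <- smoothLateral(membraneChannel(sim$stack), width = 10)
  cm <- detectApicalContour(sm)
  est <- estimateCellHeight(cm, zBasal = 40, axial = 0.2)
  true <- estimateCellHeight(contourMap(sim$masks), zBasal = 40, axial = 0.2)
  expect_lt(abs(est - true), 0.2)
})

test_that("batch localization aggregates per group and reports actual n", {
  sims <- c(lapply(1:2, function(i)
    simulateConfocalStack(nx = 16, ny = 16, nz = 40, enrichment = 2,
                          noiseSd = 0, seed = i)),
    lapply(3:4, function(i)
      simulateConfocalStack(nx = 16, ny = 16, nz = 40, enrichment = 1,
                            noiseSd = 0, seed = i)))
  res <- batchLocalization(lapply(sims, `[[`, "stack"),
                           groups = c("wt", "wt", "mut", "mut"))
  expect_equal(nrow(res$stacks), 4L)
  expect_equal(sort(res$groups$group), c("mut", "wt"))
  expect_equal(res$groups$n, c(2L, 2L))
  # single-stack group: aggregate equals the stack's score
  one <- batchLocalization(list(sims[[1]]$stack), groups = "solo")
  expect_equal(one$groups$ratioMean, one$stacks$ratio)
  # mixed voxel sizes within a group warn
  st2 <- simulateConfocalStack(nx = 16, ny = 16, nz = 40, voxelAxial = 0.3,
                               membraneThickness = 3.6, seed = 5)$stack
  expect_warning(batchLocalization(list(sims[[1]]$stack, st2),
                                   groups = c("g", "g")), "voxel sizes")
})
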