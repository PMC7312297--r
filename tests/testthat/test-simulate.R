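# Ground-truth properties of the synthetic-data generators: determinism,
# exact noise-free structure, and rejection of invalid specifications.

test_that("confocal stack generator encodes the enrichment ratio exactly", {
  # identity case: rho = 1, zero noise -> uniform target inside the cells
  sim1 <- simulateConfocalStack(nx = 8, ny = 8, nz = 30, enrichment = 1,
                                noiseSd = 0, seed = 1)
  tc <- targetChannel(sim1$stack)
  expect_equal(measureLocalization(tc, sim1$masks)$ratio, 1.0)
  inside <- membraneMask(sim1$masks) | cytoplasmMask(sim1$masks)
  expect_equal(length(unique(tc[inside])), 1L)

  # rho = 2, flat surface: direct computation on the generated arrays
  sim2 <- simulateConfocalStack(nx = 8, ny = 8, nz = 30, surface = "flat",
                                enrichment = 2, noiseSd = 0, seed = 1)
  tc2 <- targetChannel(sim2$stack)
  expect_equal(mean(tc2[membraneMask(sim2$masks)]) /
                 mean(tc2[cytoplasmMask(sim2$masks)]), 2.0)
})

test_that("a 2.4 um membrane band spans 12 voxels at 0.2 um axial spacing", {
  sim <- simulateConfocalStack(nx = 4, ny = 4, nz = 40, surface = "flat",
                               voxelAxial = 0.2, membraneThickness = 2.4,
                               noiseSd = 0, seed = 1)
  perColumn <- apply(membraneMask(sim$masks), c(1, 2), sum)
  expect_true(all(perColumn == 12L))
})

test_that("generators are deterministic for a fixed seed", {
  a <- simulateConfocalStack(nx = 12, ny = 12, nz = 30, seed = 42)
  b <- simulateConfocalStack(nx = 12, ny = 12, nz = 30, seed = 42)
  expect_identical(targetChannel(a$stack), targetChannel(b$stack))
  expect_identical(membraneChannel(a$stack), membraneChannel(b$stack))

  j1 <- simulateJunctionImage(nCells = 25, seed = 9)
  j2 <- simulateJunctionImage(nCells = 25, seed = 9)
  expect_identical(j1$image, j2$image)
  expect_identical(j1$junctionMask, j2$junctionMask)

  t1 <- simulateImpedanceTrace(noiseSd = 2, seed = 5)
  t2 <- simulateImpedanceTrace(noiseSd = 2, seed = 5)
  expect_identical(t1@impedance, t2@impedance)

  p1 <- simulatePhExperiment(seed = 3)
  p2 <- simulatePhExperiment(seed = 3)
  expect_identical(p1$traces$ratio, p2$traces$ratio)

  r1 <- simulatePermeabilityAssay(seed = 8)
  r2 <- simulatePermeabilityAssay(seed = 8)
  expect_identical(r1@deltaAcceptorConc, r2@deltaAcceptorConc)
})

test_that("ground-truth masks are disjoint and lie within the grid", {
  for (surf in c("flat", "step", "smooth")) {
    sim <- simulateConfocalStack(nx = 10, ny = 10, nz = 25, surface = surf,
                                 seed = 2)
    mem <- membraneMask(sim$masks); cyt <- cytoplasmMask(sim$masks)
    expect_false(any(mem & cyt))
    expect_identical(dim(mem), c(10L, 10L, 25L))
    expect_true(validObject(sim$masks))
  }
})

test_that("stack generator rejects grids too small for the membrane band", {
  expect_error(simulateConfocalStack(nx = 4, ny = 4, nz = 10,
                                     membraneThickness = 2.4,
                                     voxelAxial = 0.2),
               "too small")
})

test_that("junction image mean over the ground-truth mask equals the set intensity", {
  j <- simulateJunctionImage(nCells = 20, junctionIntensity = 200,
                             cytoplasmIntensity = 50, noiseSd = 0, seed = 4)
  expect_equal(mean(j$image[j$junctionMask]), 200)
  expect_error(simulateJunctionImage(nCells = 1), "at least 2")
  expect_warning(simulateJunctionImage(nCells = 5, junctionIntensity = 50,
                                       cytoplasmIntensity = 50, seed = 1),
                 "degenerate")
})

test_that("permeability forward model matches hand arithmetic and edge cases", {
  # Papp 7.44e-7, V_A 1.5, A 1.12, dt 1800 -> dC_A/C_D = 1.0e-3
  r <- simulatePermeabilityAssay(truePapp = 7.44e-7, donorConc = 10,
                                 acceptorVolume = 1.5, area = 1.12,
                                 duration = 1800, noiseRel = 0, seed = 1)
  expect_equal(r@deltaAcceptorConc / r@donorConc, 1.0e-3, tolerance = 1e-3)
  # zero Papp -> zero acceptor signal
  r0 <- simulatePermeabilityAssay(truePapp = 0, noiseRel = 0, seed = 1)
  expect_equal(r0@deltaAcceptorConc, 0)
  expect_error(simulatePermeabilityAssay(duration = 0), "duration")
})

test_that("impedance generator inverts exactly and honors the detergent control", {
  # constant CI 2 with zero noise
  tr <- simulateImpedanceTrace(ciTrue = function(t) rep(2, length(t)),
                               noiseSd = 0)
  expect_equal(cellIndex(tr), rep(2, length(tr@time)))
  # no cells: Rb only -> CI identically 0
  empty <- simulateImpedanceTrace(ciTrue = function(t) rep(0, length(t)),
                                  noiseSd = 0)
  expect_equal(cellIndex(empty), rep(0, length(empty@time)))
  # lethal detergent reference: effect factor 0 -> normalized CI -> 0
  det <- simulateImpedanceTrace(effectWindows = data.frame(
    start = 0.5, end = 24, factor = 0), noiseSd = 0)
  nc <- normalizeCellIndex(det)
  expect_equal(nc[det@time >= 72.5 + 1e-9], rep(0, sum(det@time >= 72.5 + 1e-9)))
  expect_error(simulateImpedanceTrace(duration = 48, treatmentTime = 72),
               "beyond")
})

test_that("pH experiment round trip and anchor-range warnings", {
  sim <- simulatePhExperiment(truePh = 7.48, ratioNoiseSd = 0, seed = 1)
  cc <- fitCalibration(sim$calibration$ph, sim$calibration$ratio)
  expect_equal(restingPh(sim$traces, cc)$mean, 7.48)
  # noisy Monte-Carlo check at the reported-precision scale
  simN <- simulatePhExperiment(truePh = 7.48, ratioNoiseSd = 0.01,
                               nRois = 14, seed = 2)
  ccN <- fitCalibration(simN$calibration$ph, simN$calibration$ratio)
  res <- restingPh(simN$traces, ccN)
  sdRoi <- 0.01 / abs(simN$slope) / sqrt(length(unique(simN$traces$time)))
  expect_lt(abs(res$mean - 7.48), 3 * sqrt(sdRoi^2 / 14 + (0.01 / 0.5)^2))
  expect_warning(simulatePhExperiment(anchors = c(5.5, 7, 8.4), seed = 1),
                 "range")
  expect_error(simulatePhExperiment(anchors = 7.0), "2 calibration anchors")
})
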