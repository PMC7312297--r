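# Synthetic-data generators with known ground truth for every pipeline
# input: confocal stacks with a known apical surface and membrane
# enrichment, junction images with a known border mask, insert permeability
# assays with a known true Papp, impedance traces with a known cell-index
# trajectory, and ratiometric pH experiments with a known true pH and
# calibration line. Noise is additive Gaussian throughout (sd configurable,
# zero allowed); every generator is deterministic for a fixed seed, and the
# noise-free output followed by the matching analysis operation recovers the
# ground-truth parameter exactly — the round-trip property the test suite
# leans on.

#' Simulate a multi-channel confocal z-stack with known ground truth
#'
#' Builds a stack whose apical surface follows a height field h(x, y)
#' (micrometres from the stack top, apical side at z = 1). The membrane
#' channel is bright in a band of `membraneThickness` micrometres starting
#' at the surface; the target channel has mean intensity
#' `enrichment * cytoplasmIntensity` inside that band and
#' `cytoplasmIntensity` in the cytoplasm below it, so the ground-truth
#' membrane/cytoplasm ratio is exactly `enrichment` before noise. Ground
#' truth masks are derived analytically from the voxelized height field.
#' Defaults emulate a polarized bronchial-epithelial culture imaged at
#' 0.2 um axial spacing with a 2.4 um (12 voxel) apical membrane band.
#'
#' Height-field presets: `"flat"` (constant `surfaceDepth`), `"step"` (two
#' flat halves separated by `surfaceAmplitude`), `"smooth"` (band-limited
#' random field: laterally smoothed white noise rescaled to
#' `surfaceDepth +/- surfaceAmplitude`).
#'
#' @param nx,ny,nz grid size in voxels; defaults 64 x 64 x 40.
#' @param voxelLateral,voxelAxial voxel size, um/px; defaults 0.2.
#' @param surface `"smooth"`, `"flat"`, `"step"`, or a numeric matrix of
#'   heights (um from the stack top).
#' @param surfaceDepth mean apical-surface depth, um; default 2.
#' @param surfaceAmplitude peak height variation, um; default 1.
#' @param surfaceScale lateral correlation scale of the smooth height
#'   field, px; default 40 (8 um at the default lateral spacing, about one
#'   cell diameter — the apical surface undulates at the cell scale).
#' @param membraneThickness membrane band thickness, um; default 2.4.
#' @param enrichment ground-truth membrane/cytoplasm intensity ratio of the
#'   target channel; default 1.7, the scale seen for apically enriched
#'   channel proteins.
#' @param cytoplasmIntensity baseline target intensity, a.u.; default 100.
#' @param membraneStainIntensity membrane-channel band intensity, a.u.;
#'   default 200.
#' @param backgroundIntensity intensity above the surface, a.u.; default 5.
#' @param noiseSd additive Gaussian noise sd, a.u.; default 10. Noisy
#'   intensities are clamped at 0 (detector floor); at the default settings
#'   the clamp is only ever active in background voxels, which belong to no
#'   mask.
#' @param seed RNG seed.
#' @return list with `stack` ([ConfocalStack-class]), `masks` (ground-truth
#'   [ApicalMaskSet-class]), `heightField` (the um height matrix) and
#'   `enrichment`.
#' @examples
#' sim <- simulateConfocalStack(nx = 16, ny = 16, nz = 40,
#'                              enrichment = 2, noiseSd = 0, seed = 7)
#' measureLocalization(sim$stack, sim$masks)$ratio   # exactly 2
#' @export
simulateConfocalStack <- function(nx = 64, ny = 64, nz = 40,
                                  voxelLateral = 0.2, voxelAxial = 0.2,
                                  surface = c("smooth", "flat", "step"),
                                  surfaceDepth = 2, surfaceAmplitude = 1,
                                  surfaceScale = 40,
                                  membraneThickness = 2.4,
                                  enrichment = 1.7,
                                  cytoplasmIntensity = 100,
                                  membraneStainIntensity = 200,
                                  backgroundIntensity = 5,
                                  noiseSd = 10, seed = 1) {
  if (nx < 1 || ny < 1 || nz < 1) stop("grid dimensions must be >= 1")
  if (enrichment <= 0) stop("enrichment ratio must be > 0")
  if (noiseSd < 0) stop("noise sd must be >= 0")
  nBand <- as.integer(round(membraneThickness / voxelAxial))
  if (nBand < 1L || nBand >= nz)
    stop("grid too small to contain the membrane band: need nz > ",
         nBand, " axial voxels")
  withr::with_seed(seed, {
    if (is.matrix(surface)) {
      h <- surface
      if (!identical(dim(h), c(nx, ny)) && !identical(dim(h), as.integer(c(nx, ny))))
        stop("surface matrix must be nx x ny")
    } else {
      surface <- match.arg(surface)
      h <- switch(surface,
        flat = matrix(surfaceDepth, nx, ny),
        step = {
          m <- matrix(surfaceDepth - surfaceAmplitude / 2, nx, ny)
          m[seq_len(nx) > nx / 2, ] <- surfaceDepth + surfaceAmplitude / 2
          m
        },
        smooth = {
          w <- matrix(stats::rnorm(nx * ny), nx, ny)
          w <- .convolveSym2d(w, .gaussKernel1d(max(2, min(surfaceScale, nx - 1, ny - 1))))
          rng <- max(abs(w - mean(w)))
          if (rng == 0) matrix(surfaceDepth, nx, ny)
          else surfaceDepth + (w - mean(w)) / rng * surfaceAmplitude
        })
    }
    maxH <- (nz - nBand) * voxelAxial
    h <- pmin(pmax(h, 0), maxH)
    zTop <- pmin(floor(h / voxelAxial) + 1L, nz - nBand + 1L)
    masks <- buildMasks(matrix(as.integer(zTop), nx, ny),
                        stripeWidth = nBand, dim = c(nx, ny, nz))
    mem3 <- membraneMask(masks)
    cyt3 <- cytoplasmMask(masks)
    membraneCh <- array(backgroundIntensity, dim = c(nx, ny, nz))
    membraneCh[mem3] <- membraneStainIntensity
    membraneCh[cyt3] <- backgroundIntensity
    targetCh <- array(backgroundIntensity, dim = c(nx, ny, nz))
    targetCh[cyt3] <- cytoplasmIntensity
    targetCh[mem3] <- enrichment * cytoplasmIntensity
    if (noiseSd > 0) {
      membraneCh <- pmax(0, membraneCh + stats::rnorm(length(membraneCh), sd = noiseSd))
      targetCh <- pmax(0, targetCh + stats::rnorm(length(targetCh), sd = noiseSd))
    }
    stack <- methods::new("ConfocalStack",
      membrane = array(membraneCh, dim = c(nx, ny, nz)),
      target = array(targetCh, dim = c(nx, ny, nz)),
      nuclei = NULL,
      voxelLateral = voxelLateral, voxelAxial = voxelAxial)
    list(stack = stack, masks = masks, heightField = h,
         enrichment = enrichment)
  })
}

#' Simulate a 2D junctional-staining image with a known border mask
#'
#' Draws a Voronoi tessellation from `nCells` random seed points: border
#' pixels (where adjacent pixels belong to different cells) form the
#' ground-truth junction mask and carry `junctionIntensity`; cell interiors
#' carry `cytoplasmIntensity`; a dark disk of radius `nucleusRadius` at each
#' cell seed emulates the unstained nucleus at `backgroundIntensity`.
#' Junction pixels are painted last, so the mask mean equals
#' `junctionIntensity` exactly before noise.
#'
#' @param nCells number of cells; must be >= 2 (no borders otherwise).
#' @param size image side length, px; default 128.
#' @param junctionIntensity border intensity, a.u.; default 200.
#' @param cytoplasmIntensity interior intensity, a.u.; default 50.
#' @param junctionWidth approximate border width, px; default 2 (each
#'   tessellation edge marks both flanking pixels; larger widths dilate).
#' @param nucleusRadius nucleus disk radius, px; default 5 (0 disables).
#' @param backgroundIntensity nucleus intensity, a.u.; default 5.
#' @param noiseSd additive Gaussian noise sd (clamped at 0); default 5.
#' @param seed RNG seed.
#' @return list with `image` (matrix), `junctionMask` (logical matrix),
#'   `labels` (cell id per pixel).
#' @export
simulateJunctionImage <- function(nCells = 25, size = 128,
                                  junctionIntensity = 200,
                                  cytoplasmIntensity = 50,
                                  junctionWidth = 2,
                                  nucleusRadius = 5,
                                  backgroundIntensity = 5,
                                  noiseSd = 5, seed = 1) {
  if (nCells < 2) stop("at least 2 cells are required to form junctions")
  if (junctionIntensity == cytoplasmIntensity)
    warning("junction and cytoplasm intensities are equal: segmentation is degenerate")
  withr::with_seed(seed, {
    sx <- stats::runif(nCells, 1, size)
    sy <- stats::runif(nCells, 1, size)
    px <- rep(seq_len(size), times = size)
    py <- rep(seq_len(size), each = size)
    best <- rep(1L, size * size)
    bestD <- (px - sx[1])^2 + (py - sy[1])^2
    for (i in seq_len(nCells)[-1]) {
      d <- (px - sx[i])^2 + (py - sy[i])^2
      upd <- d < bestD
      best[upd] <- i
      bestD[upd] <- d[upd]
    }
    labels <- matrix(best, size, size)
    mask <- matrix(FALSE, size, size)
    hdiff <- labels[-size, ] != labels[-1, ]
    mask[-size, ][hdiff] <- TRUE
    mask[-1, ][hdiff] <- TRUE
    vdiff <- labels[, -size] != labels[, -1]
    mask[, -size][vdiff] <- TRUE
    mask[, -1][vdiff] <- TRUE
    extra <- max(0L, ceiling((junctionWidth - 2) / 2))
    for (r in seq_len(extra)) {
      grown <- mask
      grown[-1, ] <- grown[-1, ] | mask[-size, ]
      grown[-size, ] <- grown[-size, ] | mask[-1, ]
      grown[, -1] <- grown[, -1] | mask[, -size]
      grown[, -size] <- grown[, -size] | mask[, -1]
      mask <- grown
    }
    img <- matrix(cytoplasmIntensity, size, size)
    if (nucleusRadius > 0) {
      for (i in seq_len(nCells)) {
        nuc <- (px - sx[i])^2 + (py - sy[i])^2 <= nucleusRadius^2
        img[matrix(nuc, size, size)] <- backgroundIntensity
      }
    }
    img[mask] <- junctionIntensity
    if (noiseSd > 0)
      img <- matrix(pmax(0, img + stats::rnorm(length(img), sd = noiseSd)),
                    size, size)
    list(image = img, junctionMask = mask, labels = labels)
  })
}

#' Simulate one insert permeability assay with known true Papp
#'
#' Forward model of the cleared-volume Papp formula under the sink
#' assumption (donor concentration constant over the short assay, donor
#' depletion ignored): the acceptor gains
#' `d[C]_A = Papp * A * [C]_D * dt / V_A`, perturbed by relative Gaussian
#' measurement noise. Defaults emulate a fluorescein assay on a 12-well
#' insert: donor 10 ug/mL, acceptor 1.5 mL, area 1.12 cm^2, 30 min.
#'
#' @param truePapp ground-truth Papp, cm/s; default 0.32e-6, the scale of a
#'   tight airway epithelial monolayer for fluorescein.
#' @param donorConc donor concentration at t = 0, ug/mL; default 10.
#' @param acceptorVolume acceptor volume, mL; default 1.5.
#' @param donorVolume donor volume, mL; default 0.5 (recorded only; the
#'   sink model does not consume it).
#' @param area insert area, cm^2; default 1.12.
#' @param duration assay duration, s; default 1800.
#' @param noiseRel relative sd of the acceptor-concentration measurement;
#'   default 0.02.
#' @param tracer label; default "fluorescein".
#' @param seed RNG seed.
#' @return a [PermeabilityRecord-class] carrying `truePapp`.
#' @examples
#' r <- simulatePermeabilityAssay(truePapp = 7.44e-7, noiseRel = 0, seed = 1)
#' computePapp(r)   # 7.44e-7
#' @export
simulatePermeabilityAssay <- function(truePapp = 0.32e-6, donorConc = 10,
                                      acceptorVolume = 1.5, donorVolume = 0.5,
                                      area = 1.12, duration = 1800,
                                      noiseRel = 0.02,
                                      tracer = "fluorescein", seed = 1) {
  if (truePapp < 0) stop("true Papp must be >= 0")
  if (duration <= 0) stop("assay duration must be > 0")
  if (min(donorConc, acceptorVolume, donorVolume, area) <= 0)
    stop("assay geometry must be strictly positive")
  withr::with_seed(seed, {
    dC <- truePapp * area * donorConc * duration / acceptorVolume
    if (noiseRel > 0) dC <- max(0, dC * (1 + stats::rnorm(1, sd = noiseRel)))
    permeabilityRecord(deltaAcceptorConc = dC, donorConc = donorConc,
                       acceptorVolume = acceptorVolume, area = area,
                       duration = duration, tracer = tracer,
                       truePapp = truePapp)
  })
}

#' Simulate a real-time impedance trace with known cell-index trajectory
#'
#' The ground-truth cell index follows a logistic growth curve
#' `CI(t) = K / (1 + exp(-r (t - lag)))`; from the treatment time onward it
#' is multiplied by window-specific effect factors (e.g. a transient dip, or
#' 0 for a lethal detergent control). Raw impedance is then generated
#' through the instrument relation `Rn(t) = Rb + 15 CI(t) + noise`, so
#' [cellIndex()] recovers the trajectory exactly in the noise-free case.
#' Defaults emulate wells sampled every 10 min over 96 h, treated at 72 h
#' (the beginning of the growth plateau) and followed for 24 h.
#'
#' @param duration trace length, h; default 96.
#' @param samplingInterval sampling interval, h; default 1/6 (10 min).
#' @param carryingCapacity,growthRate,lagTime logistic parameters (plateau
#'   CI, per-hour rate, inflection time); defaults 3, 0.15, 30.
#' @param treatmentTime treatment time, h; default 72. `NA` for an
#'   untreated well.
#' @param effectWindows data.frame with columns `start`, `end` (hours after
#'   treatment) and `factor` (multiplicative CI effect in that window);
#'   `NULL` for no effect.
#' @param rb background impedance, Ohm; default 20.
#' @param noiseSd impedance noise sd, Ohm; default 0.
#' @param ciTrue optional function of time (h) overriding the logistic
#'   ground truth entirely.
#' @param well,group labels.
#' @param seed RNG seed.
#' @return an [ImpedanceTrace-class] with the `trueCellIndex` slot filled.
#' @examples
#' tr <- simulateImpedanceTrace(ciTrue = function(t) rep(2, length(t)),
#'                              noiseSd = 0)
#' range(cellIndex(tr))   # exactly 2
#' @export
simulateImpedanceTrace <- function(duration = 96, samplingInterval = 1 / 6,
                                   carryingCapacity = 3, growthRate = 0.15,
                                   lagTime = 30, treatmentTime = 72,
                                   effectWindows = NULL, rb = 20,
                                   noiseSd = 0, ciTrue = NULL,
                                   well = "well", group = "group", seed = 1) {
  if (samplingInterval <= 0) stop("sampling interval must be > 0")
  if (rb < 0) stop("background impedance must be >= 0")
  time <- seq(0, duration, by = samplingInterval)
  if (!is.na(treatmentTime) && treatmentTime > max(time))
    stop("treatment time lies beyond the end of the trace")
  ci <- if (is.null(ciTrue))
    carryingCapacity / (1 + exp(-growthRate * (time - lagTime)))
  else ciTrue(time)
  if (!is.null(effectWindows)) {
    if (is.na(treatmentTime))
      stop("effect windows require a treatment time")
    rel <- time - treatmentTime
    for (i in seq_len(nrow(effectWindows))) {
      sel <- rel >= effectWindows$start[i] & rel <= effectWindows$end[i]
      ci[sel] <- ci[sel] * effectWindows$factor[i]
    }
  }
  withr::with_seed(seed, {
    rn <- rb + 15 * ci
    if (noiseSd > 0) rn <- rn + stats::rnorm(length(rn), sd = noiseSd)
    impedanceTrace(time = time, impedance = rn, rb = rb,
                   treatmentTime = treatmentTime, well = well,
                   group = group, trueCellIndex = ci)
  })
}

#' Simulate a ratiometric pH experiment with known true pH and calibration
#'
#' Generates (a) a calibration table of high-K+/ionophore anchor points:
#' known pH values with emission ratios on the line
#' `ratio = slope * pH + intercept` plus noise, and (b) per-ROI baseline
#' ratio traces centred on `ratio(truePh)` with the same noise model.
#' Defaults emulate a recording sampled every 2 s with 14 ROIs (cells) and
#' anchors spanning the 6.0-8.4 calibration range.
#'
#' @param truePh ground-truth resting intracellular pH; default 7.48.
#' @param anchors calibration pH values (>= 2); default
#'   `c(6.0, 6.8, 7.6, 8.4)`. Values outside 6.0-8.4 warn.
#' @param slope,intercept true calibration line; defaults 0.5 and -2.
#' @param traceLength recording length, s; default 300.
#' @param samplingPeriod sampling period, s; default 2.
#' @param ratioNoiseSd Gaussian sd of ratio measurements (traces and
#'   calibration); default 0.01.
#' @param nRois number of ROIs (cells); default 14.
#' @param seed RNG seed.
#' @return list with `traces` (data.frame roi, time, ratio), `calibration`
#'   (data.frame ph, ratio), `truePh`, `slope`, `intercept`.
#' @examples
#' sim <- simulatePhExperiment(truePh = 7.48, ratioNoiseSd = 0)
#' cc <- fitCalibration(sim$calibration$ph, sim$calibration$ratio)
#' restingPh(sim$traces, cc)$mean   # 7.48
#' @export
simulatePhExperiment <- function(truePh = 7.48,
                                 anchors = c(6.0, 6.8, 7.6, 8.4),
                                 slope = 0.5, intercept = -2,
                                 traceLength = 300, samplingPeriod = 2,
                                 ratioNoiseSd = 0.01, nRois = 14, seed = 1) {
  if (length(anchors) < 2L) stop("at least 2 calibration anchors are required")
  if (samplingPeriod <= 0) stop("sampling period must be > 0")
  if (any(anchors < 6.0 | anchors > 8.4))
    warning("calibration anchors outside the 6.0-8.4 pH range")
  withr::with_seed(seed, {
    calRatio <- slope * anchors + intercept
    if (ratioNoiseSd > 0)
      calRatio <- calRatio + stats::rnorm(length(anchors), sd = ratioNoiseSd)
    time <- seq(0, traceLength, by = samplingPeriod)
    traces <- do.call(rbind, lapply(seq_len(nRois), function(i) {
      r <- rep(slope * truePh + intercept, length(time))
      if (ratioNoiseSd > 0) r <- r + stats::rnorm(length(r), sd = ratioNoiseSd)
      data.frame(roi = sprintf("roi%02d", i), time = time, ratio = r)
    }))
    list(traces = traces,
         calibration = data.frame(ph = anchors, ratio = calRatio),
         truePh = truePh, slope = slope, intercept = intercept)
  })
}
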