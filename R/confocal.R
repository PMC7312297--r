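# Apical-surface detection and membrane/cytoplasm localization scoring in
# confocal z-stacks. The workflow mirrors standard practice for polarized
# epithelial cultures: (1) laterally smooth the membrane-stain channel,
# (2) per (x,y) column find the first z (from the apical top) whose
# intensity exceeds a fraction of the column maximum, (3) define a membrane
# stripe of fixed physical width below that contour and a cytoplasm region
# from the stripe bottom to the basal end, (4) score target-protein
# localization as mean(membrane)/mean(cytoplasm) on the raw target channel.

## truncated, renormalized 1D Gaussian; `width` is the kernel support in px
.gaussKernel1d <- function(width, sigma = width / 4) {
  half <- ceiling(width / 2)
  g <- stats::dnorm(seq(-half, half), sd = sigma)
  g / sum(g)
}

## separable 2D convolution with symmetric (reflective) padding
.convolveSym2d <- function(m, g) {
  half <- (length(g) - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  idx <- function(n) c(half:1, seq_len(n), n:(n - half + 1L))
  p <- m[idx(n1), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (i in seq_along(g)) out <- out + g[i] * p[(i - 1L) + seq_len(n1), , drop = FALSE]
  p <- out[, idx(n2), drop = FALSE]
  out <- matrix(0, n1, n2)
  for (i in seq_along(g)) out <- out + g[i] * p[, (i - 1L) + seq_len(n2), drop = FALSE]
  out
}

#' Laterally smooth a stack channel with a 2D Gaussian filter
#'
#' Convolves every z-slice of a channel with a truncated 2D Gaussian kernel.
#' Smoothing is strictly lateral: no mixing along z, so the axial intensity
#' profile that carries the apical-surface position is preserved. The kernel
#' has support `width` pixels and, by package convention, `sigma = width/4`
#' (2.5 px at the default 10 px width); it is truncated at the support and
#' renormalized to unit mass. Boundaries use symmetric (reflective) padding
#' so edge columns are not darkened, which would bias the per-column maxima
#' used downstream.
#'
#' @param x a 3D array (x, y, z), a single 2D slice, or a
#'   [ConfocalStack-class] (its membrane channel is smoothed).
#' @param width kernel support in pixels; default 10.
#' @param sigma Gaussian sigma in pixels; default `width/4`.
#' @return smoothed array of the same shape as the input channel.
#' @examples
#' sl <- matrix(runif(64), 8, 8)
#' sm <- smoothLateral(array(sl, c(8, 8, 1)), width = 4)
#' @export
smoothLateral <- function(x, width = 10, sigma = width / 4) {
  if (methods::is(x, "ConfocalStack")) x <- membraneChannel(x)
  if (width < 1) stop("smoothing width must be >= 1 pixel")
  wasMatrix <- is.matrix(x)
  if (wasMatrix) x <- array(x, dim = c(dim(x), 1L))
  dm <- dim(x)
  if (length(dm) != 3L) stop("x must be a 2D matrix or 3D array")
  if (width > min(dm[1:2]))
    stop("smoothing width exceeds the lateral slice size")
  g <- .gaussKernel1d(width, sigma)
  out <- x
  for (z in seq_len(dm[3]))
    out[, , z] <- .convolveSym2d(x[, , z, drop = TRUE], g)
  if (wasMatrix) out[, , 1L] else out
}

#' Detect the apical cell surface per image column
#'
#' Scans each (x, y) column of the (smoothed) membrane-stain channel from
#' the apical top (z = 1) downward and records the first z index whose
#' intensity rises strictly above `thresholdFrac` times that column's
#' maximum. Columns whose maximum falls below `backgroundFloor` times the
#' global channel maximum contain no cells and are marked background (`NA`):
#' without an absolute floor, fractional thresholding would fire on noise in
#' empty regions.
#'
#' @param x smoothed membrane channel, 3D array (x, y, z); pass the output
#'   of [smoothLateral()].
#' @param thresholdFrac fraction of the column maximum; default 0.30.
#' @param backgroundFloor fraction of the global maximum below which a
#'   column is background; default 0.05.
#' @return integer matrix (x, y) of 1-based apical z indices, `NA` for
#'   background columns.
#' @examples
#' a <- array(0, c(2, 2, 4)); a[, , 3:4] <- 10
#' detectApicalContour(a)   # all columns cross at z = 3
#' @export
detectApicalContour <- function(x, thresholdFrac = 0.30,
                                backgroundFloor = 0.05) {
  if (methods::is(x, "ConfocalStack"))
    stop("pass a smoothed channel array (see smoothLateral), not the stack")
  if (thresholdFrac <= 0 || thresholdFrac >= 1)
    stop("thresholdFrac must be in (0, 1)")
  dm <- dim(x)
  if (length(dm) != 3L) stop("x must be a 3D array")
  ncol3 <- dm[1] * dm[2]
  am <- matrix(x, nrow = ncol3)
  colmax <- am[, 1]
  for (z in seq_len(dm[3])[-1]) colmax <- pmax(colmax, am[, z])
  bg <- colmax < backgroundFloor * max(colmax)
  thr <- thresholdFrac * colmax
  zstar <- rep(NA_integer_, ncol3)
  for (z in seq_len(dm[3])) {
    hit <- is.na(zstar) & !bg & am[, z] > thr
    if (any(hit)) zstar[hit] <- z
  }
  zstar[bg] <- NA_integer_
  ## a column can remain NA without being flagged bg only if its max is
  ## <= 0 while the global max is 0 everywhere; treat it as background
  if (all(is.na(zstar))) stop("no cells detected: all columns are background")
  matrix(zstar, dm[1], dm[2])
}

#' Build membrane and cytoplasm masks from an apical contour
#'
#' Per non-background column with apical surface at z*, the membrane mask
#' covers z in \[z*, z* + stripeWidth - 1\] (clipped to the grid) — a stripe
#' of fixed width starting at the top edge of the cells — and the cytoplasm
#' mask covers z in \[z* + stripeWidth, nz\], i.e. everything between the
#' stripe bottom and the basal end of the stack. The default stripe of
#' 12 voxels corresponds to 2.4 um at 0.2 um axial spacing. Columns whose
#' cytoplasm is emptied by clipping are recorded as degenerate, not fatal.
#'
#' @param contour matrix of apical z indices from [detectApicalContour()].
#' @param stripeWidth membrane stripe width in voxels; default 12.
#' @param dim integer length-3: the stack dimensions (x, y, z).
#' @return an [ApicalMaskSet-class].
#' @examples
#' cm <- matrix(6L, 4, 4)             # flat contour at z = 6
#' m <- buildMasks(cm, stripeWidth = 12, dim = c(4, 4, 40))
#' sum(membraneMask(m)) / 16          # 12 voxels per column
#' @export
buildMasks <- function(contour, stripeWidth = 12, dim) {
  stripeWidth <- as.integer(stripeWidth)
  if (length(stripeWidth) != 1L || stripeWidth < 1L)
    stop("stripeWidth must be a single integer >= 1")
  if (length(dim) != 3L) stop("dim must be the 3D stack dimensions")
  nz <- dim[3]
  if (!identical(base::dim(contour), as.integer(dim[1:2])) &&
      !identical(base::dim(contour), dim[1:2]))
    stop("contour dimensions do not match dim[1:2]")
  c3 <- array(rep(contour, times = nz), dim = dim)
  z3 <- array(rep(seq_len(nz), each = dim[1] * dim[2]), dim = dim)
  inside <- !is.na(c3)
  mem <- inside & z3 >= c3 & z3 <= c3 + stripeWidth - 1L
  cyt <- inside & z3 >= c3 + stripeWidth
  methods::new("ApicalMaskSet",
    contour = contour,
    membrane = mem,
    cytoplasm = cyt,
    background = is.na(contour),
    degenerate = !is.na(contour) & (contour + stripeWidth > nz),
    stripeWidth = stripeWidth)
}

#' Score target-protein localization as a membrane/cytoplasm intensity ratio
#'
#' Computes mean raw target-channel intensity over the membrane and
#' cytoplasm masks and their ratio, the localization score: values above 1
#' indicate apical-membrane enrichment of the target protein. Intensities
#' are taken from the raw (unsmoothed) target channel — smoothing is only a
#' device for contour detection on the membrane stain.
#'
#' @param target raw target channel, 3D array, or a [ConfocalStack-class]
#'   (its target channel is used).
#' @param masks an [ApicalMaskSet-class].
#' @return list with `membraneMean`, `cytoplasmMean`, `ratio`,
#'   `membraneVoxels`, `cytoplasmVoxels`.
#' @examples
#' st <- simulateConfocalStack(nx = 16, ny = 16, nz = 40,
#'                             enrichment = 2, noiseSd = 0, seed = 1)
#' measureLocalization(st$stack, st$masks)$ratio   # 2
#' @export
measureLocalization <- function(target, masks) {
  if (methods::is(target, "ConfocalStack")) target <- targetChannel(target)
  if (!identical(dim(target), dim(membraneMask(masks))))
    stop("target channel and masks have different dimensions")
  nMem <- sum(membraneMask(masks))
  nCyt <- sum(cytoplasmMask(masks))
  if (nMem == 0L) stop("membrane mask is empty")
  if (nCyt == 0L)
    stop("cytoplasm mask is empty in every column; stack too shallow for the chosen stripe width")
  mMean <- mean(target[membraneMask(masks)])
  cMean <- mean(target[cytoplasmMask(masks)])
  list(membraneMean = mMean,
       cytoplasmMean = cMean,
       ratio = if (cMean > 0) mMean / cMean else NA_real_,
       membraneVoxels = nMem,
       cytoplasmVoxels = nCyt)
}

#' Estimate mean cell height from the apical contour
#'
#' Height per column is `(zBasal - z*) * axial` micrometres, averaged over
#' non-background columns. The basal reference defaults to the last z slice
#' (the stack bottom), consistent with the cytoplasm-mask convention.
#'
#' @param contour apical contour matrix from [detectApicalContour()].
#' @param zBasal 1-based basal reference z index; default the deepest slice
#'   implied by `nz`.
#' @param axial axial voxel size, um/px.
#' @param nz number of z slices (used for the default basal reference).
#' @return mean cell height in micrometres.
#' @examples
#' estimateCellHeight(matrix(6L, 2, 2), zBasal = 46, axial = 0.2)  # 8 um
#' @export
estimateCellHeight <- function(contour, zBasal = nz, axial, nz = NULL) {
  if (is.null(zBasal)) stop("supply zBasal or nz")
  ok <- !is.na(contour)
  if (!any(ok)) stop("contour contains only background columns")
  if (any(contour[ok] > zBasal))
    stop("basal reference lies above the apical contour")
  mean((zBasal - contour[ok]) * axial)
}

#' Run the localization pipeline over a set of stacks and aggregate by group
#'
#' Applies smoothing, contour detection, mask construction and localization
#' scoring to each stack and aggregates the scores per experimental group
#' (mean and sd), mirroring per-group reporting of imaging readouts. The
#' actual number of stacks per group is reported as `n`.
#'
#' @param stacks list of [ConfocalStack-class] objects.
#' @param groups character vector of group labels, one per stack.
#' @param smoothWidth,thresholdFrac,backgroundFloor,stripeWidth pipeline
#'   parameters; see [smoothLateral()], [detectApicalContour()],
#'   [buildMasks()].
#' @return list with `stacks`: per-stack data.frame (group, ratio, means,
#'   voxel counts, mean cell height), and `groups`: per-group aggregates.
#' @export
batchLocalization <- function(stacks, groups,
                              smoothWidth = 10, thresholdFrac = 0.30,
                              backgroundFloor = 0.05, stripeWidth = 12) {
  if (length(stacks) == 0L) stop("no stacks supplied")
  if (length(groups) != length(stacks))
    stop("groups must have one label per stack")
  vs <- vapply(stacks, function(s) voxelSize(s), numeric(2))
  for (g in unique(groups))
    if (nrow(unique(t(vs[, groups == g, drop = FALSE]))) > 1L)
      warning("mixed voxel sizes within group '", g, "'")
  per <- lapply(seq_along(stacks), function(i) {
    s <- stacks[[i]]
    sm <- smoothLateral(membraneChannel(s), width = smoothWidth)
    cm <- detectApicalContour(sm, thresholdFrac, backgroundFloor)
    msk <- buildMasks(cm, stripeWidth, dim = dim(membraneChannel(s)))
    sc <- measureLocalization(targetChannel(s), msk)
    data.frame(group = groups[i],
               membraneMean = sc$membraneMean,
               cytoplasmMean = sc$cytoplasmMean,
               ratio = sc$ratio,
               membraneVoxels = sc$membraneVoxels,
               cytoplasmVoxels = sc$cytoplasmVoxels,
               heightUm = estimateCellHeight(cm, axial = voxelSize(s)["axial"],
                                             nz = dim(membraneChannel(s))[3]))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  agg <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               ratioMean = mean(d$ratio), ratioSd = stats::sd(d$ratio),
               heightMean = mean(d$heightUm), heightSd = stats::sd(d$heightUm))))
  rownames(agg) <- NULL
  list(stacks = per, groups = agg)
}
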