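#' ConfocalStack: a multi-channel 3D confocal image stack
#'
#' Container for a multi-channel confocal z-stack with physical voxel
#' spacing. The z axis is oriented apical-to-basal: slice `z = 1` is the
#' apical (top) side of the specimen, slice `z = nz` the basal side, the
#' convention under which the apical contour is detected by scanning down
#' each (x, y) column.
#'
#' @slot membrane 3D numeric array (x, y, z): membrane/glycocalyx stain
#'   (e.g. WGA lectin) used for apical-surface detection.
#' @slot target 3D numeric array, same dimensions: the target-protein stain
#'   (e.g. CFTR) whose membrane/cytoplasm localization is scored.
#' @slot nuclei optional 3D numeric array (same dimensions) or `NULL`.
#' @slot voxelLateral lateral voxel size, micrometres per pixel.
#' @slot voxelAxial axial (z-step) voxel size, micrometres per pixel.
#'
#' @seealso [simulateConfocalStack()], [detectApicalContour()],
#'   [measureLocalization()]
#' @export
setClass("ConfocalStack",
  representation(
    membrane = "array",
    target = "array",
    nuclei = "ANY",
    voxelLateral = "numeric",
    voxelAxial = "numeric"
  ),
  prototype(nuclei = NULL, voxelLateral = 0.2, voxelAxial = 0.2)
)

setValidity("ConfocalStack", function(object) {
  msg <- character()
  dm <- dim(object@membrane)
  if (length(dm) != 3L) msg <- c(msg, "membrane channel must be a 3D array")
  if (!identical(dim(object@target), dm))
    msg <- c(msg, "target channel dimensions differ from membrane channel")
  if (!is.null(object@nuclei) && !identical(dim(object@nuclei), dm))
    msg <- c(msg, "nuclei channel dimensions differ from membrane channel")
  if (any(object@membrane < 0) || any(object@target < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@voxelLateral) != 1L || object@voxelLateral <= 0 ||
      length(object@voxelAxial) != 1L || object@voxelAxial <= 0)
    msg <- c(msg, "voxel sizes must be single positive numbers")
  if (length(msg)) msg else TRUE
})

#' ApicalMaskSet: apical contour plus membrane and cytoplasm voxel masks
#'
#' Result of building spatial masks from a detected apical contour. Per
#' (x, y) column the membrane mask is a stripe of `stripeWidth` voxels
#' starting at the contour; the cytoplasm mask runs from below the stripe to
#' the basal end of the stack. Columns whose membrane-stain maximum falls
#' below the background floor carry no masks (background columns); columns
#' whose cytoplasm is emptied by clipping at the stack bottom are recorded
#' in `degenerate`.
#'
#' @slot contour integer matrix (x, y): 1-based z index of the apical
#'   surface, `NA` for background columns.
#' @slot membrane,cytoplasm logical 3D arrays marking the mask voxels.
#' @slot background logical matrix (x, y): columns excluded as cell-free.
#' @slot degenerate logical matrix (x, y): columns with an empty cytoplasm
#'   mask after clipping.
#' @slot stripeWidth membrane stripe width in voxels.
#'
#' @seealso [buildMasks()], [measureLocalization()]
#' @export
setClass("ApicalMaskSet",
  representation(
    contour = "matrix",
    membrane = "array",
    cytoplasm = "array",
    background = "matrix",
    degenerate = "matrix",
    stripeWidth = "integer"
  )
)

setValidity("ApicalMaskSet", function(object) {
  msg <- character()
  dm <- dim(object@membrane)
  if (!identical(dim(object@cytoplasm), dm))
    msg <- c(msg, "membrane and cytoplasm masks must share dimensions")
  if (!identical(dim(object@contour), dm[1:2]))
    msg <- c(msg, "contour map must match the lateral mask dimensions")
  if (any(object@membrane & object@cytoplasm))
    msg <- c(msg, "membrane and cytoplasm masks must be disjoint")
  bg3 <- array(object@background, dim = dm)
  if (any((object@membrane | object@cytoplasm) & bg3))
    msg <- c(msg, "masks must exclude background columns")
  if (length(object@stripeWidth) != 1L || object@stripeWidth < 1L)
    msg <- c(msg, "stripeWidth must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' PermeabilityRecord: one insert's tracer-flux measurement
#'
#' Holds everything needed to compute an apparent permeability coefficient
#' for one culture insert and tracer: the donor concentration at t = 0, the
#' concentration gained by the acceptor compartment over the assay, the
#' acceptor volume, the insert membrane area and the assay duration.
#' Millilitres are treated as cm^3 (exact), so Papp comes out in cm/s.
#'
#' @slot tracer tracer label (e.g. "fluorescein", "albumin").
#' @slot donorConc donor concentration at t = 0, ug/mL.
#' @slot deltaAcceptorConc acceptor concentration change over the assay,
#'   ug/mL (end minus start; start is 0 for a clean acceptor compartment).
#' @slot acceptorVolume acceptor compartment volume, mL.
#' @slot area insert membrane area available for permeation, cm^2.
#' @slot duration assay duration, seconds.
#' @slot truePapp ground-truth Papp (cm/s) when the record was simulated,
#'   `NA` for measured data.
#'
#' @seealso [permeabilityRecord()], [computePapp()],
#'   [simulatePermeabilityAssay()]
#' @export
setClass("PermeabilityRecord",
  representation(
    tracer = "character",
    donorConc = "numeric",
    deltaAcceptorConc = "numeric",
    acceptorVolume = "numeric",
    area = "numeric",
    duration = "numeric",
    truePapp = "numeric"
  ),
  prototype(tracer = "tracer", truePapp = NA_real_)
)

setValidity("PermeabilityRecord", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@donorConc) || object@donorConc <= 0)
    msg <- c(msg, "donorConc must be a single positive number")
  if (!one(object@acceptorVolume) || object@acceptorVolume <= 0)
    msg <- c(msg, "acceptorVolume must be positive")
  if (!one(object@area) || object@area <= 0)
    msg <- c(msg, "area must be positive")
  if (!one(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be positive")
  if (length(object@deltaAcceptorConc) != 1L)
    msg <- c(msg, "deltaAcceptorConc must be a single number")
  if (length(msg)) msg else TRUE
})

#' ImpedanceTrace: time-stamped well impedance from a real-time cell analyzer
#'
#' Raw impedance readings for one well, the cell-free background impedance
#' and the treatment time, from which raw and normalized cell index are
#' derived. Cell index follows the instrument convention
#' CI = (Rn - Rb) / 15 with Rn the well impedance with cells and Rb the
#' background impedance of the well with medium alone.
#'
#' @slot time time points in hours, strictly increasing.
#' @slot impedance well impedance Rn(t), Ohm.
#' @slot rb background impedance Rb, Ohm.
#' @slot treatmentTime treatment time in hours (`NA` if untreated).
#' @slot well,group well and experimental-group labels.
#' @slot trueCellIndex ground-truth CI trajectory for simulated traces
#'   (length 0 for measured data).
#'
#' @seealso [impedanceTrace()], [cellIndex()], [normalizeCellIndex()],
#'   [simulateImpedanceTrace()]
#' @export
setClass("ImpedanceTrace",
  representation(
    time = "numeric",
    impedance = "numeric",
    rb = "numeric",
    treatmentTime = "numeric",
    well = "character",
    group = "character",
    trueCellIndex = "numeric"
  ),
  prototype(rb = 0, treatmentTime = NA_real_, well = "well",
            group = "group", trueCellIndex = numeric())
)

setValidity("ImpedanceTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@impedance))
    msg <- c(msg, "time and impedance must have equal length")
  if (length(object@time) && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@rb) != 1L || object@rb < 0)
    msg <- c(msg, "rb must be a single non-negative number")
  if (length(object@trueCellIndex) &&
      length(object@trueCellIndex) != length(object@time))
    msg <- c(msg, "trueCellIndex must match the trace length")
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: linear emission-ratio vs pH calibration
#'
#' Least-squares fit of dye emission ratio on pH from high-K+/nigericin
#' calibration solutions of known pH: ratio = slope * pH + intercept. The
#' validity range is the pH span of the anchors; conversions outside it are
#' flagged as extrapolation.
#'
#' @slot anchors data.frame with columns `ph` and `ratio`.
#' @slot slope,intercept fitted line coefficients (ratio per pH unit; a.u.).
#' @slot residualSd residual standard deviation of the fit.
#' @slot range numeric length-2: validity range (min, max anchor pH).
#'
#' @seealso [fitCalibration()], [ratioToPh()], [restingPh()]
#' @export
setClass("CalibrationCurve",
  representation(
    anchors = "data.frame",
    slope = "numeric",
    intercept = "numeric",
    residualSd = "numeric",
    range = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (nrow(object@anchors) < 2L)
    msg <- c(msg, "at least 2 calibration anchors are required")
  if (!all(c("ph", "ratio") %in% names(object@anchors)))
    msg <- c(msg, "anchors must have columns 'ph' and 'ratio'")
  if (length(object@slope) != 1L || object@slope == 0)
    msg <- c(msg, "fitted slope must be a single non-zero number (monotone mapping)")
  if (length(object@range) != 2L || object@range[1] > object@range[2])
    msg <- c(msg, "range must be (min, max)")
  if (length(msg)) msg else TRUE
})
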