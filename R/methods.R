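#' @rdname stack-accessors
#' @export
setMethod("membraneChannel", "ConfocalStack", function(x) x@membrane)

#' @rdname stack-accessors
#' @export
setMethod("targetChannel", "ConfocalStack", function(x) x@target)

#' @rdname stack-accessors
#' @export
setMethod("nucleiChannel", "ConfocalStack", function(x) x@nuclei)

#' @rdname stack-accessors
#' @export
setMethod("voxelSize", "ConfocalStack", function(x)
  c(lateral = x@voxelLateral, axial = x@voxelAxial))

#' @rdname mask-accessors
#' @export
setMethod("contourMap", "ApicalMaskSet", function(x) x@contour)

#' @rdname mask-accessors
#' @export
setMethod("membraneMask", "ApicalMaskSet", function(x) x@membrane)

#' @rdname mask-accessors
#' @export
setMethod("cytoplasmMask", "ApicalMaskSet", function(x) x@cytoplasm)

#' @rdname mask-accessors
#' @export
setMethod("backgroundColumns", "ApicalMaskSet", function(x) x@background)

#' @rdname mask-accessors
#' @export
setMethod("degenerateColumns", "ApicalMaskSet", function(x) x@degenerate)

setMethod("show", "ConfocalStack", function(object) {
  dm <- dim(object@membrane)
  cat(sprintf("ConfocalStack: %d x %d x %d voxels (apical at z = 1)\n",
              dm[1], dm[2], dm[3]))
  cat(sprintf("  voxel size: %.3g um lateral, %.3g um axial\n",
              object@voxelLateral, object@voxelAxial))
  cat(sprintf("  channels: membrane, target%s\n",
              if (is.null(object@nuclei)) "" else ", nuclei"))
  invisible(NULL)
})

setMethod("show", "ApicalMaskSet", function(object) {
  dm <- dim(object@membrane)
  cat(sprintf("ApicalMaskSet: %d x %d x %d grid, stripe %d voxels\n",
              dm[1], dm[2], dm[3], object@stripeWidth))
  cat(sprintf("  membrane %d voxels | cytoplasm %d voxels | %d background, %d degenerate columns\n",
              sum(object@membrane), sum(object@cytoplasm),
              sum(object@background), sum(object@degenerate)))
  invisible(NULL)
})

setMethod("show", "PermeabilityRecord", function(object) {
  cat(sprintf("PermeabilityRecord [%s]\n", object@tracer))
  cat(sprintf("  [C]_D = %.4g ug/mL, d[C]_A = %.4g ug/mL, V_A = %.4g mL, A = %.4g cm^2, dt = %.4g s\n",
              object@donorConc, object@deltaAcceptorConc,
              object@acceptorVolume, object@area, object@duration))
  if (!is.na(object@truePapp))
    cat(sprintf("  simulated (true Papp = %.4g cm/s)\n", object@truePapp))
  invisible(NULL)
})

setMethod("show", "ImpedanceTrace", function(object) {
  cat(sprintf("ImpedanceTrace [%s / %s]: %d samples over %.3g h\n",
              object@group, object@well, length(object@time),
              if (length(object@time)) diff(range(object@time)) else 0))
  cat(sprintf("  Rb = %.4g Ohm%s\n", object@rb,
              if (is.na(object@treatmentTime)) ""
              else sprintf(", treatment at %.3g h", object@treatmentTime)))
  invisible(NULL)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: ratio = %.4g * pH + %.4g\n",
              object@slope, object@intercept))
  cat(sprintf("  %d anchors, pH range [%.3g, %.3g], residual sd %.3g\n",
              nrow(object@anchors), object@range[1], object@range[2],
              object@residualSd))
  invisible(NULL)
})
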