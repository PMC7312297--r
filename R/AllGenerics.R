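#' @rdname computePapp
#' @export
setGeneric("computePapp", function(record, ...) standardGeneric("computePapp"))

#' @rdname cellIndex
#' @export
setGeneric("cellIndex", function(trace, ...) standardGeneric("cellIndex"))

#' @rdname normalizeCellIndex
#' @export
setGeneric("normalizeCellIndex",
           function(trace, ...) standardGeneric("normalizeCellIndex"))

#' @rdname ratioToPh
#' @export
setGeneric("ratioToPh", function(curve, ratio, ...) standardGeneric("ratioToPh"))

#' Accessors for ConfocalStack channels and geometry
#'
#' @param x a [ConfocalStack-class].
#' @return `membraneChannel`, `targetChannel` and `nucleiChannel` return 3D
#'   intensity arrays (`nucleiChannel` may return `NULL`); `voxelSize`
#'   returns a named numeric `c(lateral=, axial=)` in micrometres per pixel.
#' @name stack-accessors
#' @aliases membraneChannel targetChannel nucleiChannel voxelSize
#' @examples
#' st <- simulateConfocalStack(nx = 8, ny = 8, nz = 20, seed = 1)
#' dim(membraneChannel(st$stack))
#' voxelSize(st$stack)
NULL

#' @rdname stack-accessors
#' @export
setGeneric("membraneChannel", function(x) standardGeneric("membraneChannel"))

#' @rdname stack-accessors
#' @export
setGeneric("targetChannel", function(x) standardGeneric("targetChannel"))

#' @rdname stack-accessors
#' @export
setGeneric("nucleiChannel", function(x) standardGeneric("nucleiChannel"))

#' @rdname stack-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Accessors for ApicalMaskSet components
#'
#' @param x an [ApicalMaskSet-class].
#' @return `contourMap` returns the (x, y) matrix of 1-based apical z
#'   indices (`NA` = background column); `membraneMask` and `cytoplasmMask`
#'   logical voxel arrays; `backgroundColumns` and `degenerateColumns`
#'   logical (x, y) matrices.
#' @name mask-accessors
#' @aliases contourMap membraneMask cytoplasmMask backgroundColumns
#'   degenerateColumns
NULL

#' @rdname mask-accessors
#' @export
setGeneric("contourMap", function(x) standardGeneric("contourMap"))

#' @rdname mask-accessors
#' @export
setGeneric("membraneMask", function(x) standardGeneric("membraneMask"))

#' @rdname mask-accessors
#' @export
setGeneric("cytoplasmMask", function(x) standardGeneric("cytoplasmMask"))

#' @rdname mask-accessors
#' @export
setGeneric("backgroundColumns",
           function(x) standardGeneric("backgroundColumns"))

#' @rdname mask-accessors
#' @export
setGeneric("degenerateColumns",
           function(x) standardGeneric("degenerateColumns"))
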