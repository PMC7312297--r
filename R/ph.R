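# Ratiometric intracellular-pH calibration and conversion: a linear
# emission-ratio vs pH calibration fitted from high-K+/nigericin solutions
# of known pH, inverted to convert baseline ratio traces to resting pH.

#' Fit a linear emission-ratio vs pH calibration
#'
#' Least-squares fit of `ratio = slope * pH + intercept` over calibration
#' anchors (high-K+/ionophore solutions of known pH). A linear model is the
#' package default over the usual 6.0-8.4 calibration range; the residual
#' sd and the validity range (the anchor pH span) are recorded on the
#' curve. Anchors outside 6.0-8.4 trigger a warning (outside the standard
#' calibration range for this dye class), as do anchor ratios that are not
#' monotone in pH beyond twice the fit's residual sd.
#'
#' @param ph anchor pH values (>= 2, distinct).
#' @param ratio measured emission ratios at each anchor.
#' @return a [CalibrationCurve-class].
#' @examples
#' cc <- fitCalibration(c(6, 7, 8), 0.5 * c(6, 7, 8) - 2)
#' c(cc@slope, cc@intercept)   # 0.5, -2
#' @export
fitCalibration <- function(ph, ratio) {
  if (length(ph) < 2L || length(ratio) != length(ph))
    stop("at least 2 (pH, ratio) anchors are required")
  if (length(unique(ph)) < 2L)
    stop("calibration anchors must span at least 2 distinct pH values")
  if (any(ph < 6.0 | ph > 8.4))
    warning("calibration anchors outside the 6.0-8.4 pH range")
  fit <- stats::lm(ratio ~ ph)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope == 0) stop("degenerate calibration: zero slope")
  resid <- unname(stats::residuals(fit))
  residualSd <- if (length(ph) > 2L) stats::sd(resid) else 0
  o <- order(ph)
  d <- diff(ratio[o])
  if (any(sign(d) == -sign(slope) & abs(d) > 2 * residualSd))
    warning("anchor ratios are non-monotone in pH beyond the fit noise")
  methods::new("CalibrationCurve",
    anchors = data.frame(ph = ph, ratio = ratio),
    slope = slope, intercept = intercept,
    residualSd = residualSd, range = range(ph))
}

#' Convert emission ratios to pH using a fitted calibration
#'
#' Inverts the linear calibration: `pH = (ratio - intercept) / slope`.
#' Results outside the calibration's validity range are flagged via a
#' warning and an `"extrapolated"` attribute.
#'
#' @param curve a [CalibrationCurve-class].
#' @param ratio emission ratio(s) to convert.
#' @param ... unused.
#' @return pH value(s), with attribute `extrapolated` (logical vector).
#' @examples
#' cc <- fitCalibration(c(6, 8.4), 0.5 * c(6, 8.4) - 2)
#' ratioToPh(cc, 1.74)   # 7.48
#' @rdname ratioToPh
#' @export
setMethod("ratioToPh", "CalibrationCurve", function(curve, ratio, ...) {
  ph <- (ratio - curve@intercept) / curve@slope
  out <- ph < curve@range[1] | ph > curve@range[2]
  if (any(out))
    warning(sum(out), " value(s) outside the calibrated pH range [",
            curve@range[1], ", ", curve@range[2], "]; extrapolating")
  attr(ph, "extrapolated") <- out
  ph
})

#' Resting intracellular pH from baseline ratio traces
#'
#' For each ROI, averages the emission ratio over the baseline window (the
#' start of the recording, while cells are perfused with plain buffer) and
#' converts it to pH through the calibration; then summarizes across ROIs,
#' the unit of replication for this readout.
#'
#' @param traces data.frame with columns `roi`, `time` (s), `ratio`.
#' @param curve a [CalibrationCurve-class].
#' @param baselineWindow numeric length-2, seconds; default the first 60 s.
#' @return list with `perRoi` (data.frame roi, meanRatio, ph), `mean`,
#'   `sd`, `n` across ROIs.
#' @export
restingPh <- function(traces, curve, baselineWindow = c(0, 60)) {
  if (!all(c("roi", "time", "ratio") %in% names(traces)))
    stop("traces must have columns roi, time, ratio")
  sel <- traces$time >= baselineWindow[1] & traces$time <= baselineWindow[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- traces[sel, ]
  meanRatio <- tapply(base$ratio, base$roi, mean)
  ph <- suppressWarnings(as.numeric(ratioToPh(curve, as.numeric(meanRatio))))
  perRoi <- data.frame(roi = names(meanRatio),
                       meanRatio = as.numeric(meanRatio), ph = ph,
                       row.names = NULL)
  list(perRoi = perRoi, mean = mean(ph), sd = stats::sd(ph),
       n = nrow(perRoi))
}
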