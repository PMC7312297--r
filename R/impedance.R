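# Real-time impedance readouts: cell index, treatment-anchored
# normalization, kinetic-window summaries and viability calls.

#' Construct an ImpedanceTrace
#'
#' @param time time points in hours, strictly increasing.
#' @param impedance well impedance Rn(t), Ohm.
#' @param rb background impedance (well with medium alone), Ohm.
#' @param treatmentTime treatment time in hours; `NA` for untreated wells.
#' @param well,group labels.
#' @param trueCellIndex optional ground-truth CI trajectory (simulation).
#' @return an [ImpedanceTrace-class].
#' @export
impedanceTrace <- function(time, impedance, rb = 0, treatmentTime = NA_real_,
                           well = "well", group = "group",
                           trueCellIndex = numeric()) {
  methods::new("ImpedanceTrace", time = time, impedance = impedance,
               rb = rb, treatmentTime = treatmentTime, well = well,
               group = group, trueCellIndex = trueCellIndex)
}

#' Cell index from raw impedance
#'
#' The instrument convention for single-frequency real-time cell analysis:
#' `CI(t) = (Rn(t) - Rb) / 15`, with Rn the well impedance with cells and
#' Rb the background impedance of the well with medium alone. The divisor
#' 15 is the instrument's fixed scale factor.
#'
#' @param trace an [ImpedanceTrace-class].
#' @param ... unused.
#' @return numeric cell-index series, same length as the trace.
#' @examples
#' tr <- impedanceTrace(time = 1, impedance = 45, rb = 15)
#' cellIndex(tr)   # 2
#' @rdname cellIndex
#' @export
setMethod("cellIndex", "ImpedanceTrace", function(trace, ...) {
  (trace@impedance - trace@rb) / 15
})

#' Normalize a cell-index series at the treatment time
#'
#' Divides the series by its value at the last sample at or before the
#' treatment time, so the anchor sample is exactly 1. Treatments are applied
#' at the beginning of the growth plateau, making the pre-treatment sample
#' the natural reference; normalization cancels both Rb and the 1/15 scale,
#' so treated and control wells are directly comparable.
#'
#' @param trace an [ImpedanceTrace-class], or a numeric CI series (then
#'   supply `time` and `treatmentTime`).
#' @param time,treatmentTime time vector (h) and treatment time (h) when
#'   `trace` is a plain numeric series.
#' @param ... unused.
#' @return normalized cell-index series.
#' @rdname normalizeCellIndex
#' @export
setMethod("normalizeCellIndex", "ImpedanceTrace", function(trace, ...) {
  if (is.na(trace@treatmentTime))
    stop("trace has no treatment time to anchor on")
  .normalizeCI(cellIndex(trace), trace@time, trace@treatmentTime)
})

#' @rdname normalizeCellIndex
#' @export
setMethod("normalizeCellIndex", "numeric",
          function(trace, time, treatmentTime, ...) {
  .normalizeCI(trace, time, treatmentTime)
})

.normalizeCI <- function(ci, time, treatmentTime) {
  if (length(ci) != length(time)) stop("ci and time must have equal length")
  idx <- which(time <= treatmentTime)
  if (length(idx) == 0L)
    stop("no sample at or before the treatment time")
  anchor <- ci[max(idx)]
  if (anchor <= 0)
    stop("anchor cell index <= 0: cannot normalize an empty or dead well")
  ci / anchor
}

#' Summarize a kinetic window of a (normalized) cell-index series
#'
#' Arithmetic mean and sd of samples with time in `[window[1], window[2]]`
#' hours. Typical windows for a 24 h treatment follow-up are 6-15 h (early
#' response) and 16-24 h (recovery), measured from treatment.
#'
#' @param ci numeric (normalized) cell-index series.
#' @param time time vector, hours.
#' @param window numeric length-2 `(tStart, tEnd)` in hours.
#' @return list with `mean`, `sd`, `n`.
#' @export
summarizeWindow <- function(ci, time, window) {
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be (tStart, tEnd) with tStart <= tEnd")
  if (window[1] < min(time) || window[2] > max(time))
    stop("window extends beyond the trace span")
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("no samples fall inside the window")
  list(mean = mean(ci[sel]), sd = stats::sd(ci[sel]), n = sum(sel))
}

#' Classify a treated well as viable, transiently affected, or lethal
#'
#' Rule-based call on a normalized cell-index series, relative to windows
#' measured from the treatment time: lethal if the terminal-window mean has
#' fallen to the lethal reference level (the detergent-control level, or an
#' absolute threshold) plus `lethalMargin`; transient if an intermediate
#' window departs from 1 by more than `effectMargin` but the terminal window
#' has recovered to within `effectMargin` of 1; viable otherwise.
#'
#' @param ci normalized cell-index series.
#' @param time time vector, hours.
#' @param treatmentTime treatment time, hours.
#' @param lethalThreshold absolute normalized-CI level marking cell death
#'   (e.g. the terminal mean of a detergent-control well). Required.
#' @param earlyWindow,lateWindow windows in hours after treatment; defaults
#'   6-15 h and 16-24 h.
#' @param effectMargin relative departure from control counted as an
#'   effect; default 0.20.
#' @param lethalMargin tolerance above the lethal reference; default 0.10.
#' @return one of `"viable"`, `"transient_effect"`, `"lethal"`.
#' @export
viabilityCall <- function(ci, time, treatmentTime, lethalThreshold,
                          earlyWindow = c(6, 15), lateWindow = c(16, 24),
                          effectMargin = 0.20, lethalMargin = 0.10) {
  if (missing(lethalThreshold) || is.null(lethalThreshold) ||
      !is.finite(lethalThreshold))
    stop("a lethal reference threshold is required (detergent control level)")
  rel <- time - treatmentTime
  early <- summarizeWindow(ci, rel, earlyWindow)
  late <- summarizeWindow(ci, rel, lateWindow)
  if (late$mean <= lethalThreshold + lethalMargin) return("lethal")
  earlyEffect <- abs(early$mean - 1) > effectMargin
  lateRecovered <- abs(late$mean - 1) <= effectMargin
  if (earlyEffect && lateRecovered) "transient_effect" else "viable"
}
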