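# TEER and apparent-permeability computation for culture-insert barrier
# assays. Unit conventions: resistances in Ohm, areas in cm^2, volumes in
# mL (treated as cm^3, exact), concentrations in ug/mL (they cancel in the
# Papp formula), durations in seconds, so Papp comes out in cm/s.

#' Compute TEER as a blank-subtracted resistance-area product
#'
#' Transepithelial electrical resistance is expressed relative to the
#' monolayer surface area: `(raw - blank) * area` in Ohm.cm^2. The blank is
#' the resistance of a cell-free insert; its default (85 Ohm on a 1.12 cm^2
#' insert) corresponds to the typical 90-100 Ohm.cm^2 cell-free band.
#' Negative results are returned with a warning rather than rejected — a
#' blank exceeding the sample signals a measurement problem worth surfacing,
#' not hiding.
#'
#' @param raw measured resistance, Ohm (vectorized).
#' @param blank cell-free insert resistance, Ohm; default 85.
#' @param area insert membrane area, cm^2; default 1.12.
#' @return TEER in Ohm.cm^2.
#' @examples
#' computeTEER(700, blank = 95, area = 1.12)   # 677.6
#' @export
computeTEER <- function(raw, blank = 85, area = 1.12) {
  if (length(area) != 1L || !is.finite(area) || area <= 0)
    stop("area must be a single positive number (cm^2)")
  if (any(blank < 0)) stop("blank resistance must be >= 0")
  teer <- (raw - blank) * area
  if (any(teer < 0))
    warning("negative TEER: blank exceeds measured resistance for ",
            sum(teer < 0), " reading(s)")
  teer
}

#' Convert a fluorescence reading to tracer concentration
#'
#' Inverts a standard curve by blank-subtracted linear least squares:
#' `fluorescence - blank ~ concentration` is fitted over the standards and
#' solved for the unknown. Readings below the blank floor at 0 ug/mL with a
#' warning (plate-reader noise near blank); readings outside the calibrated
#' fluorescence range warn about extrapolation.
#'
#' @param concentrations standard concentrations, ug/mL (>= 2 values).
#' @param fluorescence standard readings, a.u., monotone in concentration.
#' @param reading reading(s) to convert, a.u.
#' @param blank blank (zero-concentration) reading, a.u.; default 0.
#' @return concentration(s) in ug/mL.
#' @examples
#' fluorescenceToConcentration(c(0, 10), c(0, 1000), reading = 500)  # 5
#' @export
fluorescenceToConcentration <- function(concentrations, fluorescence,
                                        reading, blank = 0) {
  if (length(concentrations) < 2L)
    stop("at least 2 standards are required")
  if (length(fluorescence) != length(concentrations))
    stop("concentrations and fluorescence must have equal length")
  o <- order(concentrations)
  d <- diff(fluorescence[o])
  if (!(all(d > 0) || all(d < 0)))
    stop("standard readings are not monotone in concentration")
  fit <- stats::lm(I(fluorescence - blank) ~ concentrations)
  a <- stats::coef(fit)[2]
  b <- stats::coef(fit)[1]
  if (a == 0) stop("flat standard curve: cannot invert")
  net <- reading - blank
  low <- net < 0
  if (any(low))
    warning(sum(low), " reading(s) below blank; floored at 0 ug/mL")
  conc <- pmax(0, (net - b) / a)
  rng <- range(fluorescence - blank)
  if (any(net > rng[2] | net < rng[1]))
    warning("reading outside the calibrated range; extrapolating")
  unname(conc)
}

#' Construct a PermeabilityRecord
#'
#' @param deltaAcceptorConc acceptor concentration change over the assay,
#'   ug/mL. Negative measured values are clamped to 0 with a warning
#'   (plate-reader noise near blank), preserving the record for audit.
#' @param donorConc donor concentration at t = 0, ug/mL.
#' @param acceptorVolume acceptor volume, mL; default 1.5.
#' @param area insert area, cm^2; default 1.12.
#' @param duration assay duration, s.
#' @param tracer tracer label.
#' @param truePapp ground-truth Papp for simulated records; `NA` otherwise.
#' @return a [PermeabilityRecord-class].
#' @export
permeabilityRecord <- function(deltaAcceptorConc, donorConc,
                               acceptorVolume = 1.5, area = 1.12,
                               duration, tracer = "tracer",
                               truePapp = NA_real_) {
  if (deltaAcceptorConc < 0) {
    warning("negative acceptor concentration change clamped to 0")
    deltaAcceptorConc <- 0
  }
  methods::new("PermeabilityRecord",
    tracer = tracer, donorConc = donorConc,
    deltaAcceptorConc = deltaAcceptorConc,
    acceptorVolume = acceptorVolume, area = area,
    duration = duration, truePapp = truePapp)
}

#' Apparent permeability coefficient from one insert assay
#'
#' Computes `Papp = (d[C]_A * V_A) / (A * [C]_D * dt)` in cm/s from the
#' cleared-volume formulation: the acceptor concentration gain `d[C]_A`
#' times the acceptor volume is the cleared donor volume, normalized by
#' membrane area, donor concentration at t = 0 and assay duration. The
#' sink assumption (donor concentration constant over the short assay) is
#' built into the formula.
#'
#' @param record a [PermeabilityRecord-class].
#' @param ... unused.
#' @return Papp in cm/s.
#' @examples
#' r <- permeabilityRecord(deltaAcceptorConc = 0.01, donorConc = 10,
#'                         acceptorVolume = 1.5, area = 1.12, duration = 1800)
#' computePapp(r)   # 7.44e-7 cm/s
#' @rdname computePapp
#' @export
setMethod("computePapp", "PermeabilityRecord", function(record, ...) {
  (record@deltaAcceptorConc * record@acceptorVolume) /
    (record@area * record@donorConc * record@duration)
})

#' Express measurements as a percentage of a control group
#'
#' Each value is scaled by `100 / mean(control)`, the reporting convention
#' for treatment effects on TEER and permeability: the control group's own
#' mean maps to 100%.
#'
#' @param values numeric measurements.
#' @param control numeric control-group measurements (non-empty, non-zero
#'   mean).
#' @return percentages of the control mean.
#' @examples
#' percentOfControl(1.0, c(2, 2))   # 50
#' @export
percentOfControl <- function(values, control) {
  if (length(control) == 0L) stop("control group is empty")
  m <- mean(control)
  if (!is.finite(m) || m == 0) stop("control mean is zero or undefined")
  100 * values / m
}
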