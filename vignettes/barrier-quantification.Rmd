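---
title: "Quantifying epithelial barrier models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial barrier models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpiBarrier)
```

EpiBarrier computes the standard quantitative readouts of cultured
bronchial-epithelial barrier models — the kind of polarized airway
monolayers (e.g. CFBE cells expressing wild-type or ΔF508 CFTR) grown on
permeable inserts and characterized functionally, electrically and by
fluorescence microscopy. This vignette explains each method, the
assumptions behind it, the parameters that matter, and the design choices
made where the underlying conventions are not fully standardized.

## Barrier function: TEER and apparent permeability

Transepithelial electrical resistance reports the tightness of the
paracellular cleft. A raw volt-ohmmeter reading contains the cell-free
insert's resistance, so `computeTEER()` subtracts a blank and multiplies by
the membrane area:

$$\mathrm{TEER} = (R_\mathrm{raw} - R_\mathrm{blank}) \times A
\quad [\Omega\,\mathrm{cm}^2].$$

The default blank (85 Ω on a 1.12 cm² insert) corresponds to the typical
90–100 Ω·cm² cell-free band. Negative results are returned with a warning:
a blank exceeding the sample is a measurement problem the user should see.

Tracer flux across the monolayer is summarized by the apparent permeability
coefficient computed from the cleared volume:

$$P_\mathrm{app} = \frac{\Delta [C]_A \, V_A}{A \, [C]_D \, \Delta t}
\quad [\mathrm{cm/s}],$$

where $\Delta [C]_A$ is the tracer concentration gained by the acceptor
compartment over the assay, $V_A$ the acceptor volume (default 1.5 mL),
$A$ the insert area (default 1.12 cm²), $[C]_D$ the donor concentration at
$t=0$ and $\Delta t$ the assay duration. Millilitres are treated as cm³
(exact), and the concentration units cancel. Two modelling choices are
deliberate:

* **Sink assumption.** The donor concentration is taken as constant over
  the assay. For a tight monolayer and a 30–60 min assay the donor loses a
  fraction on the order of $10^{-3}$ of its tracer, so donor depletion is
  negligible; the forward simulator makes the same assumption, so the
  round trip is exact by construction and its validity is a documented
  approximation, not a hidden one.
* **Negative measured $\Delta [C]_A$** (possible when the acceptor reads
  near blank) is clamped to zero with a warning rather than rejected —
  plate-reader noise near the detection floor is routine, and discarding
  such inserts would bias group means upward.

Per-insert $P_\mathrm{app}$ is computed first and aggregated afterwards
(rather than averaging duplicate wells before the computation); with the
formula linear in $\Delta[C]_A$ the two orders agree for equal-geometry
replicates, and per-insert values keep the dispersion visible.

`percentOfControl()` implements the reporting convention for treatment
effects: each value is scaled by 100 over the control-group mean.

```{r}
r <- permeabilityRecord(deltaAcceptorConc = 0.01, donorConc = 10,
                        acceptorVolume = 1.5, area = 1.12, duration = 1800)
computePapp(r)          # 7.44e-7 cm/s
computeTEER(700, blank = 95, area = 1.12)
```

## Impedance kinetics and viability

Real-time cell analyzers report a dimensionless cell index derived from
the well impedance at a single frequency:
$\mathrm{CI}(t) = (R_n(t) - R_b)/15$, with $R_n$ the impedance with cells,
$R_b$ the background impedance of the medium-only well and 15 Ω the
instrument's fixed scale. `normalizeCellIndex()` divides the series by its
value at the last sample at or before the treatment time. The anchor
convention is a design choice: "normalized cell index" is not formally
defined by the instrument literature, but treatments are applied at the
beginning of the growth plateau, so the last pre-treatment sample is the
natural reference, and anchoring there cancels both $R_b$ and the 1/15
scale. An optional division by the control-group trajectory was considered
and left out of the default: it conflates control drift with treatment
response and is easy to apply downstream if wanted.

`viabilityCall()` turns a normalized trace into one of
`viable` / `transient_effect` / `lethal` using two windows after treatment
(defaults 6–15 h and 16–24 h, the windows in which transient bicarbonate
responses and their recovery are visible in this assay class) and two
explicit margins: an effect is a >20% departure of the early-window mean
from 1, and lethality is a terminal mean within 0.10 of the lethal
reference (a detergent-control level such as Triton X-100, which the user
must supply — the package refuses to guess it). The thresholds are
configurable because the published calls they mirror are qualitative.

## Confocal localization: apical membrane vs cytoplasm

The localization score for an apically targeted channel protein is the
ratio of mean target-stain intensity in an apical membrane stripe to that
in the cytoplasm below it. The pipeline:

1. **Lateral smoothing** (`smoothLateral()`): each z-slice of the
   membrane-glycocalyx channel (e.g. WGA lectin) is convolved with a 2D
   Gaussian of 10 px support. "10-pixel-wide" names a width, not a sigma;
   the package convention is $\sigma = \mathrm{width}/4$ (2.5 px), kernel
   truncated at the support and renormalized to unit mass. Padding is
   symmetric (reflective): zero padding would darken edge columns and bias
   their maxima. Smoothing is strictly lateral so the axial profile that
   carries the surface position is untouched, and it is applied only to
   the membrane channel — intensities are always measured on the raw
   target channel.
2. **Contour detection** (`detectApicalContour()`): per (x, y) column,
   scanning from the apical top, the first z whose smoothed intensity
   rises *strictly above* 30% of the column maximum (ties resolve to the
   smallest z — the literal first crossing). Columns whose maximum is
   below 5% of the global maximum are background: a purely fractional
   threshold would fire on noise in cell-free regions. Column maxima are
   taken on the smoothed data, consistent with detecting on the smoothed
   stack.
3. **Masks** (`buildMasks()`): membrane = a 12-voxel (2.4 µm at 0.2 µm
   axial spacing) stripe from the contour down; cytoplasm = everything
   from the stripe bottom to the basal end of the stack. Columns whose
   cytoplasm is emptied by clipping are recorded, not fatal; masks,
   above-contour region and background columns partition the grid.
4. **Scoring** (`measureLocalization()`, `batchLocalization()`): mask
   means on the raw target channel, their ratio, and per-group mean ± sd
   with the actual n reported.

`estimateCellHeight()` reconstructs mean cell height as
$(z_\mathrm{basal} - z^*) \times$ axial spacing averaged over
non-background columns, with the basal reference defaulting to the stack
bottom (matching the cytoplasm-mask convention) and overridable when a
detected basal plane is available. The axial 0.2 µm/px default is inferred
from the 12 px ≙ 2.4 µm stripe equivalence and stays configurable, as does
everything above (`thresholdFrac`, `backgroundFloor`, `stripeWidth`,
smoothing width and sigma).

## Junctional staining intensity

Junction proteins (ZO-1, E-cadherin, β-catenin) form bright pericellular
belts. `segmentJunctions()` clusters raw pixel intensities (the only
feature — the method is intensity-based by design) with k-means and takes
the highest-mean cluster as the junctional mask; `k = 3` by default
(background, cytoplasm, junction — real images contain unstained regions),
`k = 2` for background-free crops. The implementation is `stats::kmeans`
(Hartigan–Wong) under a fixed seed with 25 random starts, which on 1-D
intensity data reliably attains the global within-cluster sum-of-squares
optimum (the test suite checks this against exhaustive enumeration).
Cluster identity is made stable by relabeling in ascending mean order.
Nuclei pixels are not excluded by default; constant images are rejected as
degenerate rather than silently returning an arbitrary partition.
`junctionalMeanIntensity()` is computed per image and then averaged per
group, keeping the image as the replication unit.

## Ratiometric intracellular pH

A pH-sensitive dual-excitation dye (BCECF class) yields a 495/436 emission
ratio that is mapped to pH through calibration points recorded in
high-K⁺/nigericin solutions of known pH. `fitCalibration()` fits
`ratio = slope · pH + intercept` by least squares; a linear model is the
default because over the 6.0–8.4 calibration range the dye response is
close to linear and two-point calibrations (common in practice) determine
a line exactly. The full sigmoidal titration model was considered and
rejected as the default: it needs ≥ 4 well-spread anchors to be
identifiable, which the workflow does not guarantee. Anchors outside
6.0–8.4 and non-monotone anchor sequences (beyond twice the residual sd)
warn. `ratioToPh()` inverts the line and flags extrapolation beyond the
anchor span. `restingPh()` averages each ROI's ratio over a baseline
window — the first 60 s by default, since "the beginning of the
measurement" is qualitative and 30 samples at the 2 s sampling period
average the ratio noise down by ~5× — converts per ROI, and summarizes
across ROIs (the replication unit for this readout).

## Group statistics

`oneWayAnova()` wraps the classical fixed-effects decomposition
(`stats::aov`), flagging the doubly-degenerate all-constant case instead
of returning 0/0. `dunnettTest()` implements many-to-one comparisons with
a pooled variance; the family-wise adjustment refers each |t| to the null
distribution of the *maximum* |t| across the correlated comparisons,
sampled by seeded Monte Carlo (`dunnettCritical()`). Monte Carlo was
chosen over numerical integration of the multivariate t because it is
dimension-agnostic for arbitrary (unbalanced) group sizes and directly
testable — the suite checks convergence under doubling, agreement with
`multcomp`'s single-step values, and empirical family-wise error
0.05 ± 0.01 under null simulation. `twoWayAnovaBonferroni()` fits the
two-factor model with interaction (classical decomposition when balanced,
Type-II sums of squares via `car::Anova` otherwise — the choice only
matters for unbalanced user data and is reported in the output), tests
requested cell contrasts on the pooled error and Bonferroni-multiplies
their p values. Variance homogeneity is assumed throughout, mirroring the
classical tests; there is no Welch option in scope. Significance tiers
follow the `*` < 0.05, `**` < 0.01, `***` < 0.001 convention.

## The synthetic-data generator

Every analysis input can be simulated with known ground truth, which is
how the package validates itself end to end:

* `simulateConfocalStack()` builds a stack over a height field h(x, y):
  flat, step, or a band-limited random field whose lateral correlation
  scale defaults to 40 px (8 µm — apical surfaces undulate at the cell
  scale, not pixel to pixel). Defaults: 64×64×40 voxels at 0.2 µm spacing,
  2.4 µm membrane band, target-channel enrichment ratio 1.7 (the scale
  observed for apically enriched channel proteins), cytoplasm 100 a.u.,
  membrane stain 200 a.u., background 5 a.u., additive Gaussian noise
  sd 10. Masks are derived analytically from the voxelized height field,
  and intensities are painted from the masks, so the noise-free
  membrane/cytoplasm ratio equals the enrichment parameter exactly.
* `simulateJunctionImage()` draws a Voronoi tessellation of cells, marks
  border pixels as the ground-truth junction mask (≈2 px wide, dilatable),
  adds dark nucleus disks, and paints junction pixels last so the mask
  mean equals the set junction intensity before noise.
* `simulatePermeabilityAssay()` runs the Papp formula forward under the
  sink assumption with relative measurement noise (default 2%).
* `simulateImpedanceTrace()` generates a logistic cell-index trajectory
  (plateau CI 3, rate 0.15 h⁻¹, inflection 30 h; sampled every 10 min over
  96 h, treatment at 72 h — the plateau onset) with multiplicative effect
  windows (a 0 factor emulates the lethal detergent control), then maps it
  through Rn = Rb + 15·CI + noise so the analysis inverts it exactly at
  zero noise.
* `simulatePhExperiment()` generates calibration anchors on a known line
  (defaults: slope 0.5 per pH unit, intercept −2, anchors 6.0–8.4) and
  per-ROI baseline traces around ratio(true pH), 14 ROIs sampled every 2 s.

Noise is additive Gaussian everywhere (clamped at the zero detector floor,
which at default settings only ever triggers in background voxels) — the
simplest defensible model, and declared. All generators are deterministic
given a seed.

What the generator does *not* emulate, deliberately: point-spread-function
blur, photobleaching, shading, chromatic shift, cell-to-cell biological
variability, or growth biology beyond a logistic curve. Passing the
recovery tests therefore demonstrates that the analysis is correct and
unbiased *given* the stated image-formation model, not that it is robust
to every real-microscope artifact; the configurable thresholds exist
precisely because real data will need them.

## Numerical choices and problem sizes

Contour detection resolves ties toward the smaller z; k-means uses a fixed
seed and multi-start; Dunnett critical values use 10⁵ Monte-Carlo draws by
default (≈0.5% quantile precision, and reusable across datasets of the
same design via the `nullSample` argument). The validation suite runs
contour recovery on 256×256×40 stacks (the field size of a typical
high-NA confocal frame), ratio recovery on 64×64×40 stacks over an
enrichment grid of 0.5–3, 1000-replicate permeability and pH noise
studies, and 10,000-replicate null simulations for the family-wise error
of both post-hoc procedures.

## Known limitations

* The localization score is a field-level summary; there is no per-cell
  instance segmentation, deconvolution or registration.
* The linear pH calibration extrapolates poorly outside the anchor span
  (it flags, but cannot fix, out-of-range ratios).
* The lethality/effect margins of `viabilityCall()` are conventions, not
  fitted quantities.
* Lateral smoothing biases contour detection on steeply sloped surfaces
  (it mixes columns of different heights); with surfaces undulating at the
  cell scale the error stays within one axial voxel, but pathological
  geometries (steps aligned with the grid) can locally exceed it.
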