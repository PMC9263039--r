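---
title: "Quantitative phase cytotoxicity assays: models and methods"
author: "holoassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phase cytotoxicity assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoassay)
```

# Overview

`holoassay` implements a label-free cytotoxicity assay based on digital
holographic microscopy (DHM): time-lapse off-axis holograms of adherent
epithelial cells are reconstructed into quantitative phase images (QPI), and
three readouts are derived per treatment condition:

1. the **temporal dry-mass development** of the cell population in each field
   of view (FOV),
2. the **12-h dry-mass increment** (DMI), and
3. the **fraction of rounded cells**, a circularity-based morphological
   indicator of detachment and cell death.

Because raw DHM image data for this assay type are generally not publicly
deposited, the package ships a first-class synthetic-data generator that
emulates the acquisition (96-well plate, 450 x 338 um FOV, lambda = 532 nm,
7 off-axis holograms per position every 60 min for 12 h, 3 FOVs per
condition, 3 independent experiments) and produces a complete ground-truth
manifest. Every downstream stage is therefore testable end to end: the
pipeline's readouts can be compared against the manifest they were generated
from.

# The dry-mass model

The non-aqueous (mostly protein) mass of the cells in a FOV follows from the
mean phase shift via the specific refractive increment $\alpha$:

$$dm = \frac{\lambda}{2\pi\alpha}\,\Delta\bar\varphi\; S_{\mathrm{FOV}}$$

with $\Delta\bar\varphi$ the mean phase shift over the field of view and
$S_{\mathrm{FOV}}$ its area. We use $\alpha = 0.19\ \mu m^3/pg$
(equivalently 0.19 mL/g), the standard literature value for cellular
protein; $\alpha$ is exposed in `DryMassParams()`. With
$\lambda = 0.532\ \mu m$, a uniform 0.1 rad shift over 450 x 338 um
corresponds to 6.78 ng — the unit-chain check used in the test suite.

Two conventions matter and are fixed package-wide:

* **Piston**: a global additive phase constant is physically meaningless;
  all reported phases are normalized so the background median is zero, and
  $\Delta\bar\varphi$ is computed after this normalization.
* **Mask geometry**: pixels excluded by apodization are treated as zeroed
  background, so the phase integral (and hence $dm$) is the valid-pixel sum
  over the full pixel count. This keeps $dm$ independent of the exact border
  mask.

Relative dry-mass development is reported by subtraction,
$DM(t) = dm(t) - dm(0)$, and the endpoint increment is
$DMI = dm_{12h} - dm_{0h}$. Subtraction (rather than division) preserves
units, makes $DMI$ equal to $DM(12h)$ exactly, and matches increments
reported in nanograms; a ratio mode is available in `relativeDM()`.
$\Delta\bar\varphi$ is taken over the whole FOV, not only over segmented
cells — debris below the segmentation size threshold therefore still
contributes to $dm$, which is the main systematic difference between the
whole-field dry mass and the sum of per-region masses under lysis. A masked
variant (`dryMass(..., cellMask = )`) is provided for sensitivity analysis.

# Hologram formation and reconstruction

## Forward model

The simulator renders scalar two-beam interference: an object wave
$A\,e^{i(\varphi + \varphi_p)}$ and a tilted plane reference at carrier
frequency $f_c$, giving intensity
$I = A^2 + R^2 + 2AR\cos(2\pi f_c\cdot x + \varphi + \varphi_p)$,
optionally after angular-spectrum propagation of the object wave to a
defocused plane. $\varphi_p$ is the parasitic interference phase: one
low-frequency sinusoid per frame whose direction rotates with the frame
index (emulating the modulated illumination of the 7-frame series) and whose
spatial offset is randomized per series — any frame-decorrelated structured
artifact exercises the averaging stage, which is its purpose. Shot noise is
applied as $I + s\sqrt{I}\,\mathcal N(0,1)$ with $s = 0.02$ by default.
The default carrier is diagonal at one third of the Nyquist frequency, the
standard compromise between sideband separability and resolution.

## Inverse pipeline

Each frame is apodized with a 10% Tukey border window (limiting spectral
leakage; the tapered border is excluded from the validity mask and from all
round-trip metrics), demodulated at the carrier, low-pass filtered with a
raised-cosine circular window (radius 0.4 x |carrier|, cosine edge over the
outer 20% — separability with minimal resolution loss, both exposed), and
inverse-transformed. The wrapped phase is unwrapped with a
reliability-sorting region-growing algorithm (edges between 4-neighbours are
merged in order of decreasing inverse second-difference reliability),
implemented in C++; it is robust on blob-like cell phase at the noise levels
the assay produces, and the algorithm choice is encapsulated behind
`unwrapPhase()`.

The seven unwrapped frames are piston-normalized (median removed), averaged
pixelwise, and the average is background-compensated once: a 2nd-order
polynomial surface is fitted to background pixels with five rounds of
robust re-classification, where the noise scale is estimated from the
*negative* flank of the residual distribution — cells only push the phase
up, so a symmetric scale estimate would absorb faint cell tails into the
background class and bias the dry mass low. Fitting the surface on the
averaged image rather than per frame is a deliberate choice: the
background/cell classification is ill-posed on single frames where the
parasitic interference dominates the residual scale, and the polynomial fit
commutes with averaging. If fewer than 20% of pixels classify as
background, the fit falls back to the border frame with a warning.

Numerical refocusing is available: exact angular-spectrum propagation with
evanescent components suppressed, and an autofocus that minimizes the
variance of the amplitude on the central region over a distance grid with
parabolic refinement. Amplitude variance replaced the more common total
variation cost here: on band-limited sideband reconstructions the
residual Gibbs ripple skews the total-variation landscape by tens of
micrometres, while the amplitude-contrast minimum stays symmetric about the
true focus. A flat cost landscape (relative variation below $10^{-3}$)
returns 0 with a warning.

# Morphometry

Cells are segmented by thresholding the compensated phase, filling holes,
8-connected labelling, and discarding regions with area at or below
350 um^2 (the debris exclusion rule). The default threshold is **fixed at
0.15 rad** — roughly ten times the post-averaging background noise.
An automatic Otsu threshold (clamped below by the same floor) is available,
but it is not the default: on sparse fields the between-class split is
dominated by the background class and lands inside the cell phase range,
so it drifts upward as cells grow, shrinking areas and dropping rounded
cells across time points. A fixed operating point keeps areas comparable
across the time series and matches the level at which the simulator
manifests its per-cell areas.

Circularity is $C = 4\pi S_{cell}/P^2$, clipped to 1; cells with $C > 0.8$
count as rounded, and the rounded fraction is the number of such cells over
all identified cells (an empty field yields a flagged missing value, never
zero). The perimeter $P$ comes from a **smoothed crack-boundary polygon**:
the exact pixel-edge boundary of each region is traced, and the vertex
chain is smoothed with a circular moving average (window 5) before summing
segment lengths. The choice is deliberate and is the single decision with
the largest effect on the rounded-cell readout: naive boundary-pixel
counting overestimates the perimeter of discs by up to ~27% and would push
circles below the $C > 0.8$ rule, corner-corrected chain codes underestimate
axis-aligned squares (pushing $\pi/4$ shapes above 0.8), and 4-direction
Crofton estimators do the same. The smoothed crack boundary keeps all three
reference shapes within ±0.02 of their analytic circularity at the assay's
pixel pitch (discs $\ge$ 0.97 from r = 15 um, squares at ~0.79, 2:1
ellipses at ~0.83).

Touching cells are *not* split (no watershed) — threshold-based single-cell
analysis of clustered cells is a recognized limitation of this assay class —
and the simulator's default placement keeps overlap rare instead.
Border-touching regions are retained by default; hole filling and border
exclusion are both exposed as flags since neither behaviour is canonical.

# The population simulator

The generator defines the study conditions; its defaults are fixed once and
are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| initial cells per FOV | 20 | 20,000 cells/mL seeded in 300 uL over a 0.34 cm^2 well is ~27 FOV-equivalents at full attachment; 20 assumes typical attachment efficiency and keeps the monolayer sub-confluent, as required for a proliferation assay |
| mean cell dry mass | 250 pg (CV 0.25) | typical for adherent lung epithelial cells |
| mean spread footprint | 1200 um^2 (CV 0.15), axis ratio 2.8–3.6 | elongated epithelial morphology; the axis-ratio floor keeps the true circularity of spread cells safely below the 0.8 threshold even after band-limit blurring |
| growth rate | 0.03/h | ~23 h population doubling time |
| mitotic rounded fraction | 0.10 | transient rounding during division, matching the order of magnitude seen in untreated controls |
| rounded footprint | 0.55 x spread area (>= 380 um^2) | mass is conserved on rounding, so the peak phase roughly doubles; the floor keeps rounded cells above the debris filter |
| debris | 2–4 fragments, 25–45% of cell mass retained, 60–150 um^2 each, scattered on an 18–32 um ring | each fragment stays below the 350 um^2 filter and resolvable from its siblings |
| susceptibility | lognormal, sdlog 0.6 | cell-to-cell variability in agent sensitivity; a resistant minority persists at high doses |
| cell phase profile | flat-top ellipse, cosine taper over the outer 50% of the radius | optically realistic smoothness: edges remain within the sideband passband of the default carrier/filter at the 512 x 384 study raster |

Agents act through Hill curves $c^h/(c^h + EC_{50}^h)$ per effect:

* **detergent** (digitonin-like; grid 0.1/5.5/20/140 ug/mL): growth
  inhibition (EC50 60, h 2), rounding (EC50 20, h 3, max 0.25/h) and lysis
  (EC50 60, h 2.5, max 0.35/h). Rounding precedes membrane rupture:
  rounded cells lyse 6x faster. This staging reproduces the
  characteristic dose profile of the rounded fraction — flat at low doses,
  rising at cytotoxic mid-doses where dying cells accumulate in the rounded
  state, then collapsing at full lysis where only debris (excluded by the
  size filter) and a small resistant, mostly spread, minority remain.
* **cytostatic** (cabazitaxel-loaded-particle-like; grid 2/8/32/128 ug/mL):
  strong rounding at low concentrations (EC50 1.5, h 1.2, max 0.25/h),
  growth inhibition (EC50 20), negligible lysis. Dry mass is conserved on
  rounding, but rounded cells stop growing, so the DMI drops while the
  rounded fraction rises.
* **inert** (unloaded-particle-like): weak effects with EC50s above
  150 ug/mL, producing measurable morphology changes only at the top of the
  concentration grid.

Lysis converts a cell's manifest row to `removed` and adds per-fragment
`debris` rows; the true population dry mass is the sum over non-removed
entities, which is what the whole-field phase integral should recover.
Per-cell mass growth is deterministic given the state history, so a control
FOV's mass ratio over 12 h equals $e^{12g}$ exactly — a closed-form oracle
used in the tests. Every stochastic draw derives from one master seed
through per-FOV sub-seeds, making all outputs bit-reproducible and
independent of evaluation order.

Manifest areas are recorded at the segmentation operating point: a cell's
`areaUm2` is the area enclosed by the 0.15 rad contour of its true phase
profile (the support-ellipse area is stored separately as
`supportAreaUm2`). Ground truth for a threshold-based segmenter is only
well-defined at a stated threshold; recording it at the pipeline's operating
point makes "area recovered within 10%" a meaningful statement.

## What the simulator does and does not emulate

It emulates: off-axis fringe formation with a controllable carrier, shot
noise, frame-decorrelated parasitic interference, defocus, proliferation,
treatment-induced rounding and lysis with dose dependence and cell-to-cell
susceptibility variation, and the plate/FOV/experiment replicate structure.

It does not emulate: partial coherence and vectorial effects, intracellular
texture (cells are smooth phase blobs), cell migration, division into
daughter cells (growth is continuous in mass), touching-cell clusters,
aberrations beyond a polynomial background, or the instrument-specific
artifact spectrum of any real DHM. Passing the acceptance checks therefore
demonstrates that the *pipeline* is correct and well-calibrated on data
whose ground truth is known, not that any particular biological effect size
in the original assay is reproduced.

# Statistical stage

Per-FOV DMIs are aggregated per condition (mean, sample SD with $n-1$,
pooled rounded fractions). Significance versus the medium control uses a
two-factor analysis of variance per condition (factors: group and
experiment) via `stats::aov`, with the experiment term dropped when only
one experiment is present; stars follow p < 0.005 (***), p < 0.01 (**),
p < 0.05 (*). Under the null with normal errors the group F-test is exact,
which the calibration test verifies empirically (type-I error 0.05 ± 0.02
over 1000 simulations).

# Numerical choices and problem sizes

* The analysis raster used throughout the tests and the acceptance script
  is 512 x 384 px over the 450 x 338 um FOV (0.88 um pitch); the full
  1024 x 770 sensor is the constructor default.
* Round-trip accuracy is measured as RMS phase error over the central 90%
  of the FOV against the known truth; the acceptance bound is 0.05 rad at
  default noise across 10 seeds.
* Parameter recovery runs 20 FOVs per arm with imaging restricted to the
  two endpoint time points (`reconstructTimepointsH`); the population
  dynamics always step hourly, so the manifest is unaffected by the imaging
  schedule. DMI only uses the endpoints, making this the natural
  problem size for bias estimation.
* Tie-breaks and degenerate inputs: empty FOVs yield zero regions and a
  flagged (missing) rounded fraction; a flat autofocus landscape returns 0
  with a warning; Otsu thresholds are clamped from below at 0.15 rad;
  circularity estimator overshoot is clipped at 1; single-FOV groups report
  a missing SD; degenerate ANOVA variance reports a missing p-value with a
  warning.

# Laboratory replication mode

The interlaboratory design is emulated as parameter perturbation only:
`labVariants` scales the initial cell count, growth rate and noise
amplitudes, and `labVariantConfig()` derives the second laboratory's
configuration with an offset seed. `interlabCompare()` reports
per-condition differences in mean DMI and rounded fraction; comparing a
result with itself yields exact zeros. A variant with 1.5x initial cells
shows systematically larger absolute DMIs with concordant rounded
fractions — the qualitative between-laboratory offset pattern — but no
attempt is made to model counting-device or handling differences, and the
mode supports no between-laboratory variance inference.

# Known limitations

* Whole-field dry mass under heavy lysis carries the debris mass that the
  region tables exclude by design; the two readouts are intentionally not
  reconcilable in the detergent arm.
* The band limit of the default carrier/filter combination sets an ~7 um
  resolution at the 512-px raster; structures smaller than that (debris
  fragments) are recovered with blurred area and reduced peak phase.
* Arg-domain demodulation is weakly nonlinear in the phase; residual
  reconstruction bias on dense, high-phase fields is below the 5% DMI
  recovery bound but not zero.
* No watershed: touching cells merge into one region, biasing per-cell
  counts when confluence is approached.
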