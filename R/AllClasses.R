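#' @import methods
#' @importFrom stats median mad rnorm runif rlnorm rpois aov fft sd setNames
#' @importFrom utils head tail write.csv read.csv
NULL

## half-width of the object spectrum the simulator can produce (cycles/um);
## the off-axis carrier must sit at least 3x this far from DC so the sideband
## is separable from the autocorrelation term
.OBJECT_SPECTRUM_HALFWIDTH <- 0.03

#' Optical and acquisition configuration of the off-axis DHM system
#'
#' Describes the interferometer geometry and noise model used both to render
#' synthetic holograms and to reconstruct quantitative phase images: laser
#' wavelength, field of view, sensor raster, off-axis carrier frequency of the
#' tilted reference wave, and the amplitudes of shot noise and the parasitic
#' (coherence-induced) interference the instrument superimposes on each frame.
#'
#' @slot wavelengthNm laser wavelength in nm.
#' @slot fovWidthUm,fovHeightUm lateral field of view in um.
#' @slot sensorCols,sensorRows sensor raster in pixels.
#' @slot carrierFreq off-axis carrier spatial frequency, cycles/um, length 2
#'   (x = columns, y = rows).
#' @slot referenceAmplitude,objectAmplitude wave amplitudes (arbitrary units).
#' @slot shotNoiseScale relative shot-noise scale applied as
#'   \code{I + s*sqrt(I)*N(0,1)}.
#' @slot parasiticFringeAmplitude amplitude (rad) of the frame-dependent
#'   parasitic interference phase.
#' @slot parasiticFringeFreq spatial frequency (cycles/um) of the parasitic
#'   pattern.
#' @slot defocusUm axial offset (um) of the object plane; 0 means in focus.
#' @seealso [OpticsConfig()]
#' @export
setClass("OpticsConfig", representation(
  wavelengthNm = "numeric",
  fovWidthUm = "numeric",
  fovHeightUm = "numeric",
  sensorCols = "integer",
  sensorRows = "integer",
  carrierFreq = "numeric",
  referenceAmplitude = "numeric",
  objectAmplitude = "numeric",
  shotNoiseScale = "numeric",
  parasiticFringeAmplitude = "numeric",
  parasiticFringeFreq = "numeric",
  defocusUm = "numeric"
))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (object@wavelengthNm <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@fovWidthUm <= 0 || object@fovHeightUm <= 0)
    msg <- c(msg, "field-of-view dimensions must be > 0")
  if (object@sensorCols < 64L || object@sensorRows < 64L)
    msg <- c(msg, "sensor raster must be at least 64 x 64 pixels")
  px <- object@fovWidthUm / object@sensorCols
  py <- object@fovHeightUm / object@sensorRows
  if (abs(px - py) / px > 0.01)
    msg <- c(msg, "pixel pitch must be square within 1%")
  if (length(object@carrierFreq) != 2L)
    msg <- c(msg, "carrierFreq must have length 2")
  else {
    fmag <- sqrt(sum(object@carrierFreq^2))
    nyq <- 1 / (2 * px)
    if (fmag <= 3 * .OBJECT_SPECTRUM_HALFWIDTH)
      msg <- c(msg, "carrier too close to DC for sideband separation")
    if (fmag >= nyq)
      msg <- c(msg, "carrier beyond the Nyquist limit")
  }
  if (object@referenceAmplitude < 0) msg <- c(msg, "referenceAmplitude < 0")
  if (object@shotNoiseScale < 0) msg <- c(msg, "shotNoiseScale < 0")
  if (length(msg)) msg else TRUE
})

#' Population, treatment and acquisition-design configuration
#'
#' Defines the simulated cell population (size, dry-mass and area
#' distributions, growth), the treatment arms (agent, concentration) with
#' their Hill-type dose-response parameters, and the time-lapse replicate
#' design (time points, fields of view per condition, independent
#' experiments).
#'
#' @slot initialCellCount cells per field of view at t = 0.
#' @slot meanCellDryMass mean single-cell dry mass (pg).
#' @slot dryMassCV lognormal coefficient of variation of single-cell dry mass.
#' @slot meanSpreadArea mean spread-cell footprint area (um^2).
#' @slot areaCV lognormal coefficient of variation of the footprint area.
#' @slot spreadEccRange axis-ratio range of spread (adherent) cells.
#' @slot roundedAreaFactor footprint-area shrinkage factor on rounding.
#' @slot growthRate exponential dry-mass growth rate of untreated spread
#'   cells (fraction/h).
#' @slot baselineRoundingFraction fraction of spread cells transiently rounded
#'   (mitosis) at any one time point in controls.
#' @slot susceptibilitySd lognormal sdlog of the per-cell susceptibility
#'   multiplier applied to agent effect rates.
#' @slot roundedLysisFactor lysis-rate multiplier for rounded cells.
#' @slot conditions data.frame with columns label, agent, concentration
#'   (ug/mL); agent is one of medium, detergent, cytostatic, inert.
#' @slot doseResponse data.frame with columns agent, effect (growth, rounding,
#'   lysis), ec50 (ug/mL), hill, max (saturating effect: dimensionless
#'   inhibition fraction for growth, per-hour rate for rounding/lysis).
#' @slot timepoints recorded time points (h), strictly increasing from 0.
#' @slot nFOV fields of view per condition and experiment.
#' @slot nExperiments independent experiment replicates.
#' @seealso [PopulationConfig()]
#' @export
setClass("PopulationConfig", representation(
  initialCellCount = "integer",
  meanCellDryMass = "numeric",
  dryMassCV = "numeric",
  meanSpreadArea = "numeric",
  areaCV = "numeric",
  spreadEccRange = "numeric",
  roundedAreaFactor = "numeric",
  growthRate = "numeric",
  baselineRoundingFraction = "numeric",
  susceptibilitySd = "numeric",
  roundedLysisFactor = "numeric",
  conditions = "data.frame",
  doseResponse = "data.frame",
  timepoints = "numeric",
  nFOV = "integer",
  nExperiments = "integer"
))

setValidity("PopulationConfig", function(object) {
  msg <- character()
  if (object@initialCellCount < 1L) msg <- c(msg, "initialCellCount must be >= 1")
  if (object@meanCellDryMass <= 0) msg <- c(msg, "meanCellDryMass must be > 0")
  if (object@meanSpreadArea <= 350)
    msg <- c(msg, "meanSpreadArea must exceed the 350 um^2 debris threshold")
  if (object@growthRate < 0) msg <- c(msg, "growthRate must be >= 0")
  if (object@baselineRoundingFraction < 0 || object@baselineRoundingFraction > 1)
    msg <- c(msg, "baselineRoundingFraction must be in [0, 1]")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (length(object@timepoints) < 1L || object@timepoints[1] != 0)
    msg <- c(msg, "timepoints must start at 0")
  need <- c("label", "agent", "concentration")
  if (!all(need %in% names(object@conditions)))
    msg <- c(msg, "conditions needs columns label, agent, concentration")
  else if (!all(object@conditions$agent %in%
                  c("medium", "detergent", "cytostatic", "inert")))
    msg <- c(msg, "unknown agent in conditions")
  needdr <- c("agent", "effect", "ec50", "hill", "max")
  if (!all(needdr %in% names(object@doseResponse)))
    msg <- c(msg, "doseResponse needs columns agent, effect, ec50, hill, max")
  else {
    if (any(object@doseResponse$ec50 <= 0)) msg <- c(msg, "ec50 must be > 0")
    if (any(object@doseResponse$hill <= 0)) msg <- c(msg, "hill must be > 0")
    if (any(object@doseResponse$max < 0)) msg <- c(msg, "max must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' A recorded off-axis hologram
#'
#' One 2D intensity image from the CMOS sensor, with the pixel geometry and
#' wavelength metadata needed for reconstruction plus acquisition provenance
#' (field of view, time point, frame index within the 7-frame series).
#'
#' @slot intensity non-negative 2D intensity array (rows x cols).
#' @slot pixelPitchUm lateral pixel pitch (um).
#' @slot wavelengthNm wavelength (nm).
#' @slot meta list of acquisition metadata (fov, timeH, frame, ...).
#' @export
setClass("Hologram", representation(
  intensity = "matrix",
  pixelPitchUm = "numeric",
  wavelengthNm = "numeric",
  meta = "list"
))

setValidity("Hologram", function(object) {
  msg <- character()
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
    msg <- c(msg, "intensity must be finite and non-negative")
  if (nrow(object@intensity) < 64L || ncol(object@intensity) < 64L)
    msg <- c(msg, "hologram must be at least 64 x 64 pixels")
  if (object@pixelPitchUm <= 0) msg <- c(msg, "pixelPitchUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' A complex object wave on the sensor grid
#'
#' Intermediate of the Fourier-transform reconstruction: amplitude and phase
#' of the demodulated object wave, on the original pixel raster.
#'
#' @slot field complex 2D array.
#' @slot pixelPitchUm lateral pixel pitch (um).
#' @slot wavelengthNm wavelength (nm).
#' @export
setClass("ComplexField", representation(
  field = "matrix",
  pixelPitchUm = "numeric",
  wavelengthNm = "numeric"
))

setValidity("ComplexField", function(object) {
  if (!is.complex(object@field)) return("field must be a complex matrix")
  if (any(!is.finite(Re(object@field))) || any(!is.finite(Im(object@field))))
    return("field must be finite everywhere")
  TRUE
})

#' A quantitative phase image
#'
#' Unwrapped, background-compensated phase map in radians over a known field
#' of view, with a validity mask for pixels excluded by apodization or
#' unresolved unwrapping.
#'
#' @slot phase 2D phase array (rad).
#' @slot pixelPitchUm lateral pixel pitch (um).
#' @slot mask logical matrix marking valid pixels.
#' @slot meta list of provenance metadata.
#' @export
setClass("PhaseImage", representation(
  phase = "matrix",
  pixelPitchUm = "numeric",
  mask = "matrix",
  meta = "list"
))

setValidity("PhaseImage", function(object) {
  msg <- character()
  if (!all(dim(object@phase) == dim(object@mask)))
    msg <- c(msg, "phase and mask geometry differ")
  if (object@pixelPitchUm <= 0) msg <- c(msg, "pixelPitchUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of the dry-mass formula
#'
#' The whole-field cellular dry mass follows from the mean phase shift as
#' \code{dm = lambda/(2*pi*alpha) * mean(phase) * S_FOV}, with the specific
#' refractive increment alpha relating protein concentration to refractive
#' index elevation.
#'
#' @slot alpha specific refractive increment (um^3/pg); 0.19 um^3/pg
#'   (= 0.19 mL/g) for cellular protein.
#' @slot wavelengthUm wavelength (um).
#' @seealso [DryMassParams()], [dryMass()]
#' @export
setClass("DryMassParams", representation(
  alpha = "numeric",
  wavelengthUm = "numeric"
))

setValidity("DryMassParams", function(object) {
  if (object@alpha <= 0 || object@wavelengthUm <= 0)
    return("alpha and wavelength must be > 0")
  TRUE
})

#' Parameters of threshold-based cell segmentation
#'
#' @slot thresholdMethod "otsu" (automatic, with a noise floor) or "fixed".
#' @slot fixedThreshold threshold (rad) when thresholdMethod = "fixed".
#' @slot thresholdFloor lower bound (rad) applied to the automatic threshold.
#' @slot minArea region-size threshold (um^2); regions with
#'   \code{S_cell <= minArea} are discarded as debris.
#' @slot fillHoles fill interior holes before labelling.
#' @slot cRound circularity threshold above which a cell counts as rounded.
#' @slot excludeBorder drop regions touching the image border.
#' @slot smoothWindow vertex window of the perimeter estimator (odd).
#' @seealso [SegmentationParams()], [segmentCells()]
#' @export
setClass("SegmentationParams", representation(
  thresholdMethod = "character",
  fixedThreshold = "numeric",
  thresholdFloor = "numeric",
  minArea = "numeric",
  fillHoles = "logical",
  cRound = "numeric",
  excludeBorder = "logical",
  smoothWindow = "integer"
))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    msg <- c(msg, "thresholdMethod must be 'otsu' or 'fixed'")
  if (object@minArea <= 0) msg <- c(msg, "minArea must be > 0")
  if (object@cRound <= 0 || object@cRound >= 1)
    msg <- c(msg, "cRound must be in (0, 1)")
  if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
    msg <- c(msg, "smoothWindow must be a positive odd integer")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated assay
#'
#' Long-format manifest of the simulator: one row per cell (or debris
#' fragment) per recorded time point, and a per-FOV table of the true
#' population dry mass.
#'
#' @slot cells data.frame: experiment, condition, agent, concentration, fov,
#'   timeH, id, parent, state (spread/rounded/debris/removed), dryMassPg,
#'   xUm, yUm, areaUm2 (area above the segmentation floor), supportAreaUm2,
#'   ecc, theta, circularity.
#' @slot fov data.frame: experiment, condition, agent, concentration, fov,
#'   timeH, truePopulationDryMassPg, nCells, roundedFraction.
#' @export
setClass("GroundTruth", representation(
  cells = "data.frame",
  fov = "data.frame"
))

#' A simulated DHM assay (manifest + lazily rendered images)
#'
#' Holds the configuration, seed and ground-truth manifest of a simulated
#' time-lapse experiment.  Phase maps and holograms are rendered on demand
#' from the manifest with [truthPhase()] and [renderHologram()], so the
#' object stays small regardless of the imaging raster.
#'
#' @slot optics an [OpticsConfig-class].
#' @slot population a [PopulationConfig-class].
#' @slot truth a [GroundTruth-class].
#' @slot seed integer master seed.
#' @export
setClass("SimulatedAssay", representation(
  optics = "OpticsConfig",
  population = "PopulationConfig",
  truth = "GroundTruth",
  seed = "integer"
))

#' Full assay configuration
#'
#' @slot optics an [OpticsConfig-class].
#' @slot population a [PopulationConfig-class].
#' @slot segmentation a [SegmentationParams-class].
#' @slot drymass a [DryMassParams-class].
#' @slot labVariants data.frame of parameter perturbations emulating
#'   laboratory-to-laboratory differences (label, cellCountFactor,
#'   growthFactor, noiseFactor), or an empty data.frame.
#' @slot seed integer master seed.
#' @export
setClass("AssayConfig", representation(
  optics = "OpticsConfig",
  population = "PopulationConfig",
  segmentation = "SegmentationParams",
  drymass = "DryMassParams",
  labVariants = "data.frame",
  seed = "integer"
))

setValidity("AssayConfig", function(object) {
  lv <- object@labVariants
  if (nrow(lv) && anyDuplicated(lv$label))
    return("labVariants labels must be distinct")
  TRUE
})

#' Result of a full assay run
#'
#' @slot fovSeries data.frame, one row per FOV x time point (dry mass etc.).
#' @slot fovSummary data.frame, one row per FOV (DMI, rounded fraction).
#' @slot conditionSummary data.frame, one row per condition (mean DMI +- sd,
#'   pooled rounded fraction, significance vs the medium control).
#' @slot regions data.frame of segmented cell regions at the endpoint.
#' @slot truth the [GroundTruth-class] of the underlying simulation.
#' @slot config the [AssayConfig-class] that produced the result.
#' @slot log data.frame of per-stage records and warnings.
#' @export
setClass("AssayResult", representation(
  fovSeries = "data.frame",
  fovSummary = "data.frame",
  conditionSummary = "data.frame",
  regions = "data.frame",
  truth = "GroundTruth",
  config = "AssayConfig",
  log = "data.frame"
))

## ---- show methods -------------------------------------------------------

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig\n",
      sprintf("  wavelength: %g nm | FOV: %g x %g um | sensor: %d x %d px\n",
              object@wavelengthNm, object@fovWidthUm, object@fovHeightUm,
              object@sensorCols, object@sensorRows),
      sprintf("  pixel pitch: %.4f um | carrier: (%.4f, %.4f) cycles/um\n",
              object@fovWidthUm / object@sensorCols,
              object@carrierFreq[1], object@carrierFreq[2]),
      sprintf("  shot noise: %g | parasitic: %g rad @ %g cycles/um | defocus: %g um\n",
              object@shotNoiseScale, object@parasiticFringeAmplitude,
              object@parasiticFringeFreq, object@defocusUm), sep = "")
})

setMethod("show", "PopulationConfig", function(object) {
  cat("PopulationConfig\n",
      sprintf("  %d cells/FOV | %g pg mean dry mass | %g um^2 mean spread area\n",
              object@initialCellCount, object@meanCellDryMass,
              object@meanSpreadArea),
      sprintf("  growth %g/h | %d conditions | %d FOV x %d experiments | %d time points\n",
              object@growthRate, nrow(object@conditions), object@nFOV,
              object@nExperiments, length(object@timepoints)), sep = "")
})

setMethod("show", "Hologram", function(object) {
  cat(sprintf("Hologram %d x %d px, pitch %.4f um, lambda %g nm\n",
              nrow(object@intensity), ncol(object@intensity),
              object@pixelPitchUm, object@wavelengthNm))
})

setMethod("show", "ComplexField", function(object) {
  cat(sprintf("ComplexField %d x %d px, pitch %.4f um\n",
              nrow(object@field), ncol(object@field), object@pixelPitchUm))
})

setMethod("show", "PhaseImage", function(object) {
  v <- object@phase[object@mask]
  cat(sprintf("PhaseImage %d x %d px, pitch %.4f um, S_FOV %.0f um^2\n",
              nrow(object@phase), ncol(object@phase), object@pixelPitchUm,
              fovArea(object)),
      sprintf("  phase range [%.3f, %.3f] rad, %.1f%% valid\n",
              min(v), max(v), 100 * mean(object@mask)), sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cell-time records, %d FOV-time records\n",
              nrow(object@cells), nrow(object@fov)))
})

setMethod("show", "SimulatedAssay", function(object) {
  cat("SimulatedAssay (seed ", object@seed, ")\n", sep = "")
  show(object@population)
  show(object@truth)
})

setMethod("show", "AssayResult", function(object) {
  cat("AssayResult\n")
  print(object@conditionSummary)
})
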