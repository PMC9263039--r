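## Constructors, accessors and small shared generics.

#' Construct an optics/acquisition configuration
#'
#' Defaults describe the study instrument: a 532 nm off-axis DHM with a
#' 450 x 338 um field of view.  When `carrierFreq` is omitted a diagonal
#' carrier at one third of the Nyquist frequency is chosen, the standard
#' compromise between sideband separability and spatial resolution.
#'
#' @param wavelengthNm laser wavelength (nm).
#' @param fovWidthUm,fovHeightUm field of view (um).
#' @param sensorCols,sensorRows sensor raster (pixels).
#' @param carrierFreq off-axis carrier (cycles/um, length 2) or NULL for the
#'   diagonal default.
#' @param referenceAmplitude,objectAmplitude wave amplitudes.
#' @param shotNoiseScale relative shot-noise scale.
#' @param parasiticFringeAmplitude parasitic interference amplitude (rad).
#' @param parasiticFringeFreq parasitic pattern frequency (cycles/um).
#' @param defocusUm axial object-plane offset (um).
#' @return an [OpticsConfig-class] object.
#' @examples
#' opt <- OpticsConfig(sensorCols = 512, sensorRows = 384)
#' pixelPitch(opt)
#' @export
OpticsConfig <- function(wavelengthNm = 532,
                         fovWidthUm = 450, fovHeightUm = 338,
                         sensorCols = 1024L, sensorRows = 770L,
                         carrierFreq = NULL,
                         referenceAmplitude = 1, objectAmplitude = 1,
                         shotNoiseScale = 0.02,
                         parasiticFringeAmplitude = 0.08,
                         parasiticFringeFreq = 0.012,
                         defocusUm = 0) {
  pitch <- fovWidthUm / sensorCols
  if (is.null(carrierFreq)) {
    nyq <- 1 / (2 * pitch)
    carrierFreq <- c(1, 1) / sqrt(2) * nyq / 3
  }
  new("OpticsConfig",
      wavelengthNm = wavelengthNm,
      fovWidthUm = fovWidthUm, fovHeightUm = fovHeightUm,
      sensorCols = as.integer(sensorCols), sensorRows = as.integer(sensorRows),
      carrierFreq = carrierFreq,
      referenceAmplitude = referenceAmplitude,
      objectAmplitude = objectAmplitude,
      shotNoiseScale = shotNoiseScale,
      parasiticFringeAmplitude = parasiticFringeAmplitude,
      parasiticFringeFreq = parasiticFringeFreq,
      defocusUm = defocusUm)
}

.defaultConditions <- function() {
  data.frame(
    label = c("medium",
              paste0("digitonin_", c(0.1, 5.5, 20, 140)),
              paste0("paca_", c(2, 8, 32, 128)),
              paste0("paca_cbz_", c(2, 8, 32, 128))),
    agent = c("medium", rep("detergent", 4), rep("inert", 4),
              rep("cytostatic", 4)),
    concentration = c(0, 0.1, 5.5, 20, 140, 2, 8, 32, 128, 2, 8, 32, 128),
    stringsAsFactors = FALSE)
}

.defaultDoseResponse <- function() {
  data.frame(
    agent  = c(rep("detergent", 3), rep("cytostatic", 3), rep("inert", 3)),
    effect = rep(c("growth", "rounding", "lysis"), 3),
    ec50   = c(60, 20, 60,    20, 1.5, 500,   200, 150, 250),
    hill   = c(2, 3, 2.5,     1.5, 1.2, 2,    2, 2, 2.5),
    max    = c(1, 0.25, 0.35, 1, 0.25, 0.05,  1, 0.2, 0.3),
    stringsAsFactors = FALSE)
}

#' Construct a population/treatment configuration
#'
#' Defaults emulate the study design: A549-like adherent epithelial cells
#' seeded at 20,000 cells/mL in 96-well plates (about 27 cells in a
#' 450 x 338 um field of view), imaged every 60 min for 12 h in 3 FOVs per
#' condition across 3 independent experiments, with a digitonin-like
#' detergent arm (0.1/5.5/20/140 ug/mL) and particle arms (2/8/32/128
#' ug/mL).  See the package vignette for the rationale behind each default.
#'
#' @param initialCellCount cells per FOV at t = 0.
#' @param meanCellDryMass mean single-cell dry mass (pg).
#' @param dryMassCV coefficient of variation of single-cell dry mass.
#' @param meanSpreadArea mean spread-cell footprint area (um^2).
#' @param areaCV coefficient of variation of the footprint area.
#' @param spreadEccRange axis-ratio range of spread cells.
#' @param roundedAreaFactor footprint shrinkage on rounding.
#' @param growthRate exponential growth rate (fraction/h) of untreated cells.
#' @param baselineRoundingFraction transient (mitotic) rounded fraction in
#'   controls.
#' @param susceptibilitySd lognormal sdlog of per-cell agent susceptibility.
#' @param roundedLysisFactor lysis-rate multiplier for rounded cells
#'   (rounding precedes membrane rupture in detergent-driven death).
#' @param conditions data.frame(label, agent, concentration).
#' @param doseResponse data.frame(agent, effect, ec50, hill, max).
#' @param timepoints recorded time points (h).
#' @param nFOV fields of view per condition per experiment.
#' @param nExperiments independent experiments.
#' @return a [PopulationConfig-class] object.
#' @export
PopulationConfig <- function(initialCellCount = 20L,
                             meanCellDryMass = 250,
                             dryMassCV = 0.25,
                             meanSpreadArea = 1200,
                             areaCV = 0.15,
                             spreadEccRange = c(2.8, 3.6),
                             roundedAreaFactor = 0.55,
                             growthRate = 0.03,
                             baselineRoundingFraction = 0.10,
                             susceptibilitySd = 0.6,
                             roundedLysisFactor = 6,
                             conditions = .defaultConditions(),
                             doseResponse = .defaultDoseResponse(),
                             timepoints = 0:12,
                             nFOV = 3L,
                             nExperiments = 3L) {
  new("PopulationConfig",
      initialCellCount = as.integer(initialCellCount),
      meanCellDryMass = meanCellDryMass, dryMassCV = dryMassCV,
      meanSpreadArea = meanSpreadArea, areaCV = areaCV,
      spreadEccRange = spreadEccRange,
      roundedAreaFactor = roundedAreaFactor,
      growthRate = growthRate,
      baselineRoundingFraction = baselineRoundingFraction,
      susceptibilitySd = susceptibilitySd,
      roundedLysisFactor = roundedLysisFactor,
      conditions = conditions, doseResponse = doseResponse,
      timepoints = as.numeric(timepoints),
      nFOV = as.integer(nFOV), nExperiments = as.integer(nExperiments))
}

#' Construct dry-mass formula parameters
#'
#' @param alpha specific refractive increment (um^3/pg).  The default
#'   0.19 um^3/pg equals the literature value 0.19 mL/g for cellular protein.
#' @param wavelengthUm wavelength (um).
#' @return a [DryMassParams-class] object.
#' @export
DryMassParams <- function(alpha = 0.19, wavelengthUm = 0.532) {
  new("DryMassParams", alpha = alpha, wavelengthUm = wavelengthUm)
}

#' Construct segmentation parameters
#'
#' @param thresholdMethod "fixed" (default: threshold at `fixedThreshold`,
#'   about 10x the averaged-frame background noise) or "otsu" (automatic,
#'   clamped from below by `thresholdFloor`).  On sparse fields the Otsu
#'   split is dominated by the background class and drifts into the cell
#'   phase range as cells grow, so the fixed threshold is the default.
#' @param fixedThreshold fixed threshold (rad).
#' @param thresholdFloor noise floor (rad) for the automatic threshold.
#' @param minArea debris size threshold (um^2); regions with area at or below
#'   it are excluded.
#' @param fillHoles fill interior holes before labelling.
#' @param cRound circularity threshold for rounded cells.
#' @param excludeBorder drop border-touching regions.
#' @param smoothWindow perimeter-estimator smoothing window (odd integer).
#' @return a [SegmentationParams-class] object.
#' @export
SegmentationParams <- function(thresholdMethod = c("fixed", "otsu"),
                               fixedThreshold = 0.15,
                               thresholdFloor = 0.15,
                               minArea = 350,
                               fillHoles = TRUE,
                               cRound = 0.8,
                               excludeBorder = FALSE,
                               smoothWindow = 5L) {
  new("SegmentationParams",
      thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = fixedThreshold, thresholdFloor = thresholdFloor,
      minArea = minArea, fillHoles = fillHoles, cRound = cRound,
      excludeBorder = excludeBorder, smoothWindow = as.integer(smoothWindow))
}

#' Construct a full assay configuration
#'
#' @param optics an [OpticsConfig-class].
#' @param population a [PopulationConfig-class].
#' @param segmentation a [SegmentationParams-class].
#' @param drymass a [DryMassParams-class].
#' @param labVariants optional data.frame(label, cellCountFactor,
#'   growthFactor, noiseFactor) of laboratory-emulation perturbations.
#' @param seed integer master seed.
#' @return an [AssayConfig-class] object.
#' @export
AssayConfig <- function(optics = OpticsConfig(),
                        population = PopulationConfig(),
                        segmentation = SegmentationParams(),
                        drymass = DryMassParams(),
                        labVariants = data.frame(),
                        seed = 1L) {
  new("AssayConfig", optics = optics, population = population,
      segmentation = segmentation, drymass = drymass,
      labVariants = labVariants, seed = as.integer(seed))
}

## ---- generics and accessors ---------------------------------------------

#' Pixel pitch of an imaging object
#' @param x an object carrying pixel geometry.
#' @return pixel pitch in um.
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "OpticsConfig", function(x) x@fovWidthUm / x@sensorCols)
#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "Hologram", function(x) x@pixelPitchUm)
#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ComplexField", function(x) x@pixelPitchUm)
#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "PhaseImage", function(x) x@pixelPitchUm)

#' Field-of-view area of a phase image
#' @param x a [PhaseImage-class].
#' @return S_FOV in um^2 (rows x cols x pitch^2).
#' @export
setGeneric("fovArea", function(x) standardGeneric("fovArea"))

#' @rdname fovArea
#' @export
setMethod("fovArea", "PhaseImage", function(x)
  nrow(x@phase) * ncol(x@phase) * x@pixelPitchUm^2)

#' Nyquist spatial frequency of the sensor raster
#' @param x an [OpticsConfig-class].
#' @return cycles/um.
#' @export
setGeneric("nyquistFrequency", function(x) standardGeneric("nyquistFrequency"))

#' @rdname nyquistFrequency
#' @export
setMethod("nyquistFrequency", "OpticsConfig",
          function(x) 1 / (2 * pixelPitch(x)))

#' Off-axis carrier frequency
#' @param x an [OpticsConfig-class].
#' @return cycles/um, length 2.
#' @export
setGeneric("carrierFrequency", function(x) standardGeneric("carrierFrequency"))

#' @rdname carrierFrequency
#' @export
setMethod("carrierFrequency", "OpticsConfig", function(x) x@carrierFreq)

#' Phase array of a phase image
#' @param x a [PhaseImage-class].
#' @return numeric matrix (rad).
#' @export
setGeneric("phaseArray", function(x) standardGeneric("phaseArray"))

#' @rdname phaseArray
#' @export
setMethod("phaseArray", "PhaseImage", function(x) x@phase)

#' Valid-pixel mask of a phase image
#' @param x a [PhaseImage-class].
#' @return logical matrix.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname validMask
#' @export
setMethod("validMask", "PhaseImage", function(x) x@mask)

#' Intensity array of a hologram
#' @param x a [Hologram-class].
#' @return numeric matrix.
#' @export
setGeneric("intensityArray", function(x) standardGeneric("intensityArray"))

#' @rdname intensityArray
#' @export
setMethod("intensityArray", "Hologram", function(x) x@intensity)

#' Complex array of a field
#' @param x a [ComplexField-class].
#' @return complex matrix.
#' @export
setGeneric("fieldArray", function(x) standardGeneric("fieldArray"))

#' @rdname fieldArray
#' @export
setMethod("fieldArray", "ComplexField", function(x) x@field)

#' Ground-truth tables of a simulation
#' @param x a [GroundTruth-class] or [SimulatedAssay-class].
#' @return a data.frame.
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname cellTable
#' @export
setMethod("cellTable", "GroundTruth", function(x) x@cells)
#' @rdname cellTable
#' @export
setMethod("cellTable", "SimulatedAssay", function(x) x@truth@cells)

#' @rdname cellTable
#' @export
setGeneric("fovTable", function(x) standardGeneric("fovTable"))

#' @rdname cellTable
#' @export
setMethod("fovTable", "GroundTruth", function(x) x@fov)
#' @rdname cellTable
#' @export
setMethod("fovTable", "SimulatedAssay", function(x) x@truth@fov)

#' Construct a PhaseImage
#'
#' @param phase numeric matrix (rad).
#' @param pixelPitchUm pixel pitch (um).
#' @param mask logical matrix of valid pixels (default: all valid).
#' @param meta metadata list.
#' @return a [PhaseImage-class].
#' @export
PhaseImage <- function(phase, pixelPitchUm, mask = NULL, meta = list()) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase), ncol(phase))
  new("PhaseImage", phase = phase, pixelPitchUm = pixelPitchUm,
      mask = mask, meta = meta)
}

#' Construct a Hologram
#'
#' @param intensity non-negative numeric matrix.
#' @param pixelPitchUm pixel pitch (um).
#' @param wavelengthNm wavelength (nm).
#' @param meta metadata list.
#' @return a [Hologram-class].
#' @export
Hologram <- function(intensity, pixelPitchUm, wavelengthNm = 532,
                     meta = list()) {
  new("Hologram", intensity = intensity, pixelPitchUm = pixelPitchUm,
      wavelengthNm = wavelengthNm, meta = meta)
}

#' Construct a ComplexField
#'
#' @param field complex matrix.
#' @param pixelPitchUm pixel pitch (um).
#' @param wavelengthNm wavelength (nm).
#' @return a [ComplexField-class].
#' @export
ComplexField <- function(field, pixelPitchUm, wavelengthNm = 532) {
  new("ComplexField", field = field, pixelPitchUm = pixelPitchUm,
      wavelengthNm = wavelengthNm)
}

## deterministic sub-seed derivation so every FOV/time/frame has its own
## reproducible stream regardless of evaluation order
.subSeed <- function(seed, ...) {
  idx <- c(...)
  s <- (seed %% 2147483647)
  primes <- c(48271, 1299709, 15485863, 32452843, 49979687, 67867967)
  for (i in seq_along(idx)) {
    s <- (s * 69621 + idx[i] * primes[1 + (i - 1) %% length(primes)]) %% 2147483647
  }
  as.integer(s)
}
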