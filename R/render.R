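## Off-axis hologram rendering: two-beam scalar interference of a tilted
## plane reference wave with the object wave, plus the instrument's
## frame-dependent parasitic interference and shot noise.

## cached coordinate grids (um), keyed by geometry
.gridCache <- new.env(parent = emptyenv())

.xyGrids <- function(nr, nc, pitch) {
  key <- paste(nr, nc, signif(pitch, 12), sep = "_")
  g <- .gridCache[[key]]
  if (is.null(g)) {
    g <- list(X = matrix((0:(nc - 1)) * pitch, nr, nc, byrow = TRUE),
              Y = matrix((0:(nr - 1)) * pitch, nr, nc))
    .gridCache[[key]] <- g
  }
  g
}

.freqGrids <- function(nr, nc, pitch) {
  key <- paste("f", nr, nc, signif(pitch, 12), sep = "_")
  g <- .gridCache[[key]]
  if (is.null(g)) {
    fx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1) / (nc * pitch)
    fy <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1) / (nr * pitch)
    g <- list(FX = matrix(fx, nr, nc, byrow = TRUE),
              FY = matrix(fy, nr, nc))
    .gridCache[[key]] <- g
  }
  g
}

## parasitic interference phase for one frame of the 7-frame series:
## a low-frequency sinusoidal pattern whose direction rotates with the
## frame index (emulating the modulated illumination) and whose spatial
## offset is randomized per series
.parasiticPhase <- function(optics, frameIndex, seed) {
  nr <- optics@sensorRows; nc <- optics@sensorCols
  pitch <- pixelPitch(optics)
  g <- .xyGrids(nr, nc, pitch)
  set.seed(.subSeed(seed, 104729L))
  theta0 <- runif(1, 0, pi)
  psi <- runif(7, 0, 2 * pi)
  th <- theta0 + pi * frameIndex / 7
  optics@parasiticFringeAmplitude *
    cos(2 * pi * optics@parasiticFringeFreq *
          (cos(th) * g$X + sin(th) * g$Y) + psi[frameIndex + 1L])
}

#' Render one off-axis hologram of a phase object
#'
#' Computes the two-beam interference intensity
#' \code{|O + R exp(-2i pi f.x)|^2} of the object wave
#' \code{O = A exp(i(phase + parasitic))} with a tilted plane reference at
#' the carrier frequency f, optionally propagated to a defocused plane,
#' then adds shot noise.  The 7 frames of a series share the identical cell
#' phase but differ in the parasitic interference realization and noise.
#'
#' @param phase a [PhaseImage-class] (or bare matrix, rad) covering the FOV.
#' @param optics an [OpticsConfig-class]; its raster must match `phase`.
#' @param frameIndex frame index 0..6 within the series.
#' @param seed integer seed; together with `frameIndex` it fixes the
#'   parasitic pattern and the noise.
#' @param meta metadata list stored in the hologram.
#' @return a [Hologram-class].
#' @export
renderHologram <- function(phase, optics, frameIndex = 0L, seed = 1L,
                           meta = list()) {
  validObject(optics)
  if (is(phase, "PhaseImage")) phase <- phaseArray(phase)
  nr <- optics@sensorRows; nc <- optics@sensorCols
  if (nrow(phase) != nr || ncol(phase) != nc)
    stop("phase raster does not match the sensor raster")
  if (frameIndex < 0L || frameIndex > 6L)
    stop("frameIndex must be in 0..6")
  pitch <- pixelPitch(optics)
  g <- .xyGrids(nr, nc, pitch)
  phiTot <- phase + .parasiticPhase(optics, frameIndex, seed)

  A <- optics@objectAmplitude
  R <- optics@referenceAmplitude
  carrier <- optics@carrierFreq
  if (optics@defocusUm != 0) {
    obj <- ComplexField(A * exp(1i * phiTot), pitch, optics@wavelengthNm)
    obj <- propagateField(obj, optics@defocusUm)
    O <- fieldArray(obj)
    I <- Mod(O)^2 + R^2 +
      2 * R * Re(O * exp(2i * pi * (carrier[1] * g$X + carrier[2] * g$Y)))
  } else {
    I <- A^2 + R^2 +
      2 * A * R * cos(2 * pi * (carrier[1] * g$X + carrier[2] * g$Y) + phiTot)
  }
  if (optics@shotNoiseScale > 0) {
    set.seed(.subSeed(seed, frameIndex, 224737L))
    I <- I + optics@shotNoiseScale * sqrt(pmax(I, 0)) * rnorm(length(I))
  }
  I[I < 0] <- 0
  Hologram(I, pitch, optics@wavelengthNm,
           meta = c(meta, list(frame = frameIndex, seed = seed)))
}

#' Render the 7-frame hologram series of one time point
#'
#' @inheritParams renderHologram
#' @param nFrames number of frames (default 7, the acquisition series).
#' @return list of [Hologram-class] objects.
#' @export
renderHologramSeries <- function(phase, optics, seed = 1L, nFrames = 7L,
                                 meta = list()) {
  lapply(seq_len(nFrames) - 1L, function(k)
    renderHologram(phase, optics, frameIndex = k, seed = seed, meta = meta))
}
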