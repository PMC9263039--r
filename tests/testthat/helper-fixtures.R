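# Shared fixtures: small optics rasters and geometric phase images.

# study optics on the test raster (450 x 338 um on 512 x 384 px)
testOptics <- function(...) {
  OpticsConfig(sensorCols = 512L, sensorRows = 384L, ...)
}

# even smaller raster for pipeline smoke tests
tinyOptics <- function(...) {
  OpticsConfig(sensorCols = 256L, sensorRows = 192L, ...)
}

noiseFreeOptics <- function(...) {
  testOptics(shotNoiseScale = 0, parasiticFringeAmplitude = 0, ...)
}

# phase image containing a binary shape at `level` rad on an empty field
shapePhase <- function(shapeMask, pitch, level = 1) {
  PhaseImage(shapeMask * level, pitch)
}

discMask <- function(nr, nc, cy, cx, rPx) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 < rPx^2
}

squareMask <- function(nr, nc, r0, c0, sidePx) {
  m <- matrix(FALSE, nr, nc)
  m[r0:(r0 + sidePx - 1), c0:(c0 + sidePx - 1)] <- TRUE
  m
}

ellipseMask <- function(nr, nc, cy, cx, aPx, bPx) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((cols - cx) / aPx)^2 + ((rows - cy) / bPx)^2 < 1
}

# single-condition population on a short schedule
singleConditionPop <- function(label = "medium", agent = "medium",
                               concentration = 0, ...) {
  PopulationConfig(conditions = data.frame(
    label = label, agent = agent, concentration = concentration,
    stringsAsFactors = FALSE), ...)
}

centralRegion <- function(nr, nc, frac = 0.9) {
  m <- matrix(FALSE, nr, nc)
  lo <- (1 - frac) / 2
  m[max(1, round(nr * lo)):round(nr * (1 - lo)),
    max(1, round(nc * lo)):round(nc * (1 - lo))] <- TRUE
  m
}

rmsCentral <- function(qpi, truthImg, frac = 0.9) {
  err <- phaseArray(qpi) - phaseArray(truthImg)
  sel <- centralRegion(nrow(err), ncol(err), frac) & validMask(qpi)
  sqrt(mean(err[sel]^2))
}
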