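# Hologram rendering and Fourier reconstruction: carrier location,
# demodulation round trips, propagation, autofocus, unwrapping,
# background compensation and frame averaging.

test_that("a flat-phase noise-free hologram is a pure two-beam fringe", {
  opt <- noiseFreeOptics()
  # bin-aligned carrier so the spectrum is exactly three peaks
  pitch <- pixelPitch(opt)
  fx <- 64 / (512 * pitch); fy <- 48 / (384 * pitch)
  opt@carrierFreq <- c(fx, fy)
  flat <- PhaseImage(matrix(0, 384, 512), pitch)
  h <- renderHologram(flat, opt, 0, seed = 1)
  FT <- Mod(stats::fft(intensityArray(h)))
  big <- which(FT > 1e-6 * max(FT))
  expect_length(big, 3L)  # DC and the two conjugate carrier peaks
})

test_that("zero reference amplitude gives a constant intensity", {
  opt <- noiseFreeOptics(referenceAmplitude = 0)
  blob <- PhaseImage(matrix(0.5, 384, 512), pixelPitch(opt))
  h <- renderHologram(blob, opt, 0, seed = 1)
  expect_lt(diff(range(intensityArray(h))), 1e-12)
})

test_that("carrier is located within one spectral bin", {
  opt <- noiseFreeOptics()
  flat <- PhaseImage(matrix(0, 384, 512), pixelPitch(opt))
  h <- renderHologram(flat, opt, 0, seed = 1)
  f <- locateCarrier(h)
  bin <- 1 / (384 * pixelPitch(opt))  # coarsest bin spacing
  expect_lt(max(abs(f - carrierFrequency(opt))), bin)
  # simulated cell hologram, default noise
  optN <- testOptics()
  pop <- singleConditionPop(timepoints = c(0, 12), nFOV = 1L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, optN, seed = 2)
  hc <- renderHologram(truthPhase(sim, 1, "medium", 1, 0), optN, 0, seed = 3)
  fc <- locateCarrier(hc)
  expect_lt(max(abs(fc - carrierFrequency(optN))), bin)
})

test_that("a constant image has no carrier", {
  h <- Hologram(matrix(1, 128, 128), 0.5)
  expect_error(locateCarrier(h), "no carrier")
})

test_that("a pure fringe demodulates to spatially constant phase", {
  opt <- noiseFreeOptics()
  flat <- PhaseImage(matrix(0, 384, 512), pixelPitch(opt))
  h <- renderHologram(flat, opt, 0, seed = 1)
  fld <- reconstructFourier(h, carrierFrequency(opt))
  ph <- Arg(fieldArray(fld))
  sel <- centralRegion(384, 512)
  expect_lt(sd(ph[sel]), 1e-6)
})

test_that("noise-free blob round trip recovers the phase below 0.01 rad RMS", {
  opt <- noiseFreeOptics()
  pitch <- pixelPitch(opt)
  p <- cellPhaseFootprint(600, 1500, 1.5, "spread", pitch)
  img <- matrix(0, 384, 512)
  d <- dim(p)
  img[150 + seq_len(d[1]), 220 + seq_len(d[2])] <- p
  phi <- PhaseImage(img, pitch)
  h <- renderHologram(phi, opt, 0, seed = 5)
  fld <- reconstructFourier(h, carrierFrequency(opt))
  un <- unwrapPhase(Arg(fieldArray(fld)))
  qpi <- compensateBackground(PhaseImage(un, pitch))
  expect_lt(rmsCentral(qpi, phi), 0.01)
})

test_that("sideband filter overlapping the DC disc is rejected", {
  opt <- noiseFreeOptics()
  flat <- PhaseImage(matrix(0, 384, 512), pixelPitch(opt))
  h <- renderHologram(flat, opt, 0, seed = 1)
  fmag <- sqrt(sum(carrierFrequency(opt)^2))
  expect_error(reconstructFourier(h, carrierFrequency(opt),
                                  filterRadius = fmag * 0.99),
               "DC exclusion")
})

test_that("propagation is unitary and inverts exactly", {
  opt <- testOptics()
  pitch <- pixelPitch(opt)
  set.seed(6)
  F0 <- matrix(complex(modulus = 1, argument = runif(384 * 512, -1, 1)),
               384, 512)
  fld <- ComplexField(F0, pitch, 532)
  expect_equal(fieldArray(propagateField(fld, 0)), F0)
  fwd <- propagateField(fld, 40)
  # power conservation
  expect_equal(sum(Mod(fieldArray(fwd))^2), sum(Mod(F0)^2),
               tolerance = 1e-6)
  back <- propagateField(fwd, -40)
  expect_lt(sqrt(mean(Mod(fieldArray(back) - F0)^2)), 1e-8)
})

test_that("a Gaussian beam broadens by the closed-form width law", {
  opt <- testOptics()
  pitch <- pixelPitch(opt)
  w0 <- 20; lam <- 0.532
  g <- holoassay:::.xyGrids(384L, 512L, pitch)
  X <- g$X - 512 * pitch / 2; Y <- g$Y - 384 * pitch / 2
  F0 <- exp(-(X^2 + Y^2) / w0^2) + 0i
  zR <- pi * w0^2 / lam
  z <- 2000
  out <- Mod(fieldArray(propagateField(ComplexField(F0, pitch, 532), z)))^2
  # 1/e^2 intensity radius from the second moment: w = 2 * sigma
  wx <- 2 * sqrt(sum(out * X^2) / sum(out))
  wExp <- w0 * sqrt(1 + (z / zR)^2)
  expect_equal(wx, wExp, tolerance = 0.02)
})

test_that("autofocus recovers the simulator defocus and flags flat fields", {
  opt <- noiseFreeOptics(defocusUm = 50)
  pitch <- pixelPitch(opt)
  pop <- singleConditionPop(timepoints = c(0, 12), nFOV = 1L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, opt, seed = 7)
  h <- renderHologram(truthPhase(sim, 1, "medium", 1, 0), opt, 0, seed = 8)
  fld <- reconstructFourier(h, carrierFrequency(opt))
  d <- autofocus(fld, searchRange = c(-80, 80), stepUm = 5)
  expect_equal(d, -50, tolerance = 5)
  # in-focus field: best distance within one step of zero
  opt0 <- noiseFreeOptics()
  h0 <- renderHologram(truthPhase(sim, 1, "medium", 1, 0), opt0, 0, seed = 8)
  f0 <- reconstructFourier(h0, carrierFrequency(opt0))
  expect_lt(abs(autofocus(f0, c(-40, 40), 5)), 5 + 1e-9)
  # flat (empty) field: warning and 0
  flat <- ComplexField(matrix(1 + 0i, 128, 128), pitch, 532)
  expect_warning(z0 <- autofocus(flat, c(-40, 40), 10), "flat")
  expect_identical(z0, 0)
})

test_that("unwrapping restores ramps and blobs modulo 2*pi", {
  # planar ramp reaching 6*pi
  ramp <- matrix(seq(0, 6 * pi, length.out = 200), 80, 200, byrow = TRUE)
  w <- atan2(sin(ramp), cos(ramp))
  u <- unwrapPhase(w)
  expect_lt(max(abs((u - u[1, 1]) - (ramp - ramp[1, 1]))), 1e-9)
  # result always equals input modulo 2*pi
  resid <- (u - w) / (2 * pi)
  expect_lt(max(abs(resid - round(resid))), 1e-9)
  # low blob (< pi): unchanged
  p <- cellPhaseFootprint(300, 900, 1.5, "spread", 0.88)
  expect_lt(max(p), pi)
  expect_equal(unwrapPhase(p - 0), p)
  # noisy cell with ~8 rad peak
  big <- suppressWarnings(cellPhaseFootprint(1800, 700, 1.05, "rounded", 0.88))
  expect_gt(max(big), 7)
  set.seed(9)
  noisy <- big + matrix(rnorm(length(big), sd = 0.08), nrow(big))
  uw <- unwrapPhase(atan2(sin(noisy), cos(noisy)))
  expect_lt(sqrt(mean((uw - noisy)^2)), 0.1)
})

test_that("background compensation flattens polynomial surfaces only", {
  nr <- 120; nc <- 160
  cols <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  rows <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  tilt <- 0.4 * cols - 0.25 * rows + 0.1 * cols * rows
  out <- compensateBackground(tilt, pixelPitchUm = 1)
  expect_lt(max(abs(phaseArray(out))), 1e-6)
  # blob + tilt: blob recovered, background flat
  p <- cellPhaseFootprint(500, 1200, 2, "spread", 1)
  img <- tilt
  img[40 + seq_len(nrow(p)), 60 + seq_len(ncol(p))] <-
    img[40 + seq_len(nrow(p)), 60 + seq_len(ncol(p))] + p
  blob <- matrix(0, nr, nc)
  blob[40 + seq_len(nrow(p)), 60 + seq_len(ncol(p))] <- p
  rec <- compensateBackground(img, pixelPitchUm = 1)
  expect_lt(sqrt(mean((phaseArray(rec) - blob)^2)), 0.02)
  # idempotence up to piston
  twice <- compensateBackground(rec)
  expect_lt(max(abs(phaseArray(twice) - phaseArray(rec))), 0.02)
  # background median convention
  expect_lt(abs(median(phaseArray(rec)[blob < 0.01])), 0.05)
})

test_that("frame averaging removes pistons and cancels opposed artifacts", {
  nr <- 96; nc <- 128
  base <- matrix(0, nr, nc)
  base[30:60, 40:80] <- 1.2
  f1 <- PhaseImage(base + 0.7, 1)  # piston offsets
  frames <- lapply(c(0.7, -0.3, 0.1, 0, 0.5, -0.9, 0.2), function(p)
    PhaseImage(base + p, 1))
  avg <- averagePhase(frames)
  ref <- averagePhase(list(f1, f1))
  expect_equal(phaseArray(avg), phaseArray(ref), tolerance = 1e-12)
  # two frames with opposite parasitic fringes cancel
  cols <- matrix(seq(0, 6 * pi, length.out = nc), nr, nc, byrow = TRUE)
  fr <- 0.2 * sin(cols)
  a <- averagePhase(list(PhaseImage(base + fr, 1),
                         PhaseImage(base - fr, 1)))
  resid <- phaseArray(a) - phaseArray(ref)
  expect_lt(max(abs(resid - mean(resid))), 0.1 * 0.2)
  expect_error(averagePhase(list(f1, PhaseImage(matrix(0, 10, 10), 1))),
               "geometry")
})

test_that("seven-frame averaging reduces background noise roughly by sqrt(7)", {
  opt <- testOptics()
  pop <- singleConditionPop(timepoints = c(0, 12), nFOV = 1L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, opt, seed = 19)
  phi <- truthPhase(sim, 1, "medium", 1, 0)
  holos <- renderHologramSeries(phi, opt, seed = 20)
  avg <- reconstructSeries(holos, carrierFrequency(opt))
  one <- reconstructSeries(holos[c(1, 1)], carrierFrequency(opt))
  bg <- phaseArray(phi) < 0.01 & validMask(avg) &
    centralRegion(nrow(phaseArray(phi)), ncol(phaseArray(phi)))
  rms1 <- sqrt(mean((phaseArray(one)[bg])^2))
  rms7 <- sqrt(mean((phaseArray(avg)[bg])^2))
  expect_lt(rms7, rms1)  # averaging never hurts
  expect_equal(rms7 / rms1, 1 / sqrt(7), tolerance = 0.35)
})

test_that("reconstruction is piston-invariant after compensation", {
  opt <- noiseFreeOptics()
  pitch <- pixelPitch(opt)
  pop <- singleConditionPop(timepoints = c(0, 12), nFOV = 1L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, opt, seed = 23)
  phi <- truthPhase(sim, 1, "medium", 1, 0)
  shifted <- PhaseImage(phaseArray(phi) + 0.6, pitch)
  q1 <- reconstructSeries(renderHologramSeries(phi, opt, seed = 24),
                          carrierFrequency(opt))
  q2 <- reconstructSeries(renderHologramSeries(shifted, opt, seed = 24),
                          carrierFrequency(opt))
  # invariance holds to the level of the non-rotating spectral leakage
  sel <- centralRegion(384, 512) & validMask(q1) & validMask(q2)
  expect_lt(sqrt(mean((phaseArray(q1)[sel] - phaseArray(q2)[sel])^2)), 5e-3)
})
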