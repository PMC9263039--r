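# Segmentation, circularity and the debris size filter.

test_that("circularity matches the analytic values of classic shapes", {
  expect_equal(circularity(pi * 20^2, 2 * pi * 20), 1)
  expect_equal(circularity(100, 40), pi / 4)
  # 2:1 ellipse via the Ramanujan perimeter: C ~ 0.841
  a <- 2; b <- 1
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(circularity(pi * a * b, P), 0.8412, tolerance = 1e-3)
  expect_error(circularity(0, 10))
  expect_error(circularity(10, -1))
})

test_that("estimated circularity meets the analytic targets on rasters", {
  pitch <- 450 / 1024
  seg <- function(mask) {
    s <- segmentCells(shapePhase(mask, pitch),
                      SegmentationParams(thresholdMethod = "fixed",
                                         fixedThreshold = 0.5))
    s$regions
  }
  # discs of growing radius converge to C = 1 and exceed 0.97 from 15 um
  cs <- vapply(c(15, 20, 25, 30), function(rUm) {
    seg(discMask(256, 256, 128, 128, rUm / pitch))$circularity
  }, 0)
  expect_true(all(cs >= 0.97 & cs <= 1))
  expect_gt(cs[4], cs[1] - 0.005)  # converging, allowing raster jitter
  # square: pi/4, below the rounded threshold
  sq <- seg(squareMask(384, 384, 60, 60, round(60 / pitch)))
  expect_equal(sq$circularity, pi / 4, tolerance = 0.02)
  expect_lt(sq$circularity, 0.8)
  # 2:1 ellipse: ~0.841, above the threshold
  el <- seg(ellipseMask(384, 512, 192, 256, 55 / pitch, 27.5 / pitch))
  expect_equal(el$circularity, 0.8412, tolerance = 0.02)
  expect_gt(el$circularity, 0.8)
})

test_that("the 350 um^2 size filter separates cells from debris", {
  pitch <- 450 / 1024
  # discs of 1257 um^2 (r = 20 um) and 314 um^2 (r = 10 um)
  m <- discMask(384, 512, 192, 150, 20 / pitch) |
    discMask(384, 512, 192, 380, 10 / pitch)
  s <- segmentCells(shapePhase(m, pitch),
                    SegmentationParams(thresholdMethod = "fixed",
                                       fixedThreshold = 0.5))
  expect_identical(nrow(s$regions), 1L)
  expect_equal(s$regions$areaUm2, 1257, tolerance = 0.02)
})

test_that("a blank image yields no regions and a flagged rounded fraction", {
  s <- segmentCells(PhaseImage(matrix(0, 128, 128), 0.88))
  expect_identical(nrow(s$regions), 0L)
  rf <- roundedFraction(s$regions)
  expect_true(rf$undefined)
  expect_true(is.na(rf$fraction))
})

test_that("segmentation recovers count, area and mass of simulated cells", {
  opt <- testOptics()
  pop <- singleConditionPop(timepoints = c(0, 12), nFOV = 2L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, opt, seed = 31)
  for (v in 1:2) {
    phi <- truthPhase(sim, 1, "medium", v, 0)
    s <- segmentCells(phi)
    ct <- cellTable(sim)
    man <- ct[ct$fov == v & ct$timeH == 0 & ct$state != "removed", ]
    expect_identical(nrow(s$regions), nrow(man))
    # match regions to manifest cells by centroid
    for (i in seq_len(nrow(man))) {
      j <- which.min((s$regions$xUm - man$xUm[i])^2 +
                       (s$regions$yUm - man$yUm[i])^2)
      expect_equal(s$regions$areaUm2[j], man$areaUm2[i], tolerance = 0.1)
    }
    # unit chain: per-region dry mass sums to the whole-field value within 5%
    expect_equal(sum(s$regions$dryMassPg), dryMass(phi), tolerance = 0.05)
  }
})

test_that("rounded fraction counts cells above the circularity threshold", {
  regions <- data.frame(circularity = c(0.9, 0.7, 0.85, 0.5))
  rf <- roundedFraction(regions, 0.8)
  expect_equal(rf$fraction, 0.5)
  expect_identical(rf$nRounded, 2L)
  # estimate tracks the simulator state over seeds
  opt <- testOptics()
  pop <- PopulationConfig(conditions = data.frame(
    label = "cbz", agent = "cytostatic", concentration = 8),
    nFOV = 10L, nExperiments = 1L, timepoints = c(0, 12))
  sim <- simulatePopulation(pop, opt, seed = 37)
  ct <- cellTable(sim)
  nR <- 0L; nT <- 0L; nRman <- 0L; nTman <- 0L
  for (v in 1:10) {
    s <- segmentCells(truthPhase(sim, 1, "cbz", v, 12))
    rf <- roundedFraction(s$regions)
    nR <- nR + rf$nRounded; nT <- nT + rf$nTotal
    man <- ct[ct$fov == v & ct$timeH == 12 &
                ct$state %in% c("spread", "rounded"), ]
    nRman <- nRman + sum(man$state == "rounded")
    nTman <- nTman + nrow(man)
  }
  expect_lt(abs(nR / nT - nRman / nTman), 0.1)
})

test_that("circularity is scale invariant and min-area filtering monotone", {
  pitch <- 1
  base <- segmentCells(shapePhase(ellipseMask(300, 300, 150, 150, 60, 30),
                                  pitch),
                       SegmentationParams("fixed", fixedThreshold = 0.5))
  doubled <- segmentCells(shapePhase(ellipseMask(600, 600, 300, 300, 120, 60),
                                     pitch),
                          SegmentationParams("fixed", fixedThreshold = 0.5))
  expect_equal(base$regions$circularity, doubled$regions$circularity,
               tolerance = 0.02)
  # raising min_area never increases the region count
  opt <- testOptics()
  pop <- PopulationConfig(conditions = data.frame(
    label = "dig", agent = "detergent", concentration = 30),
    nFOV = 1L, nExperiments = 1L, timepoints = c(0, 12))
  sim <- simulatePopulation(pop, opt, seed = 41)
  phi <- truthPhase(sim, 1, "dig", 1, 12)
  counts <- vapply(c(50, 150, 350, 700, 1200), function(a)
    nrow(segmentCells(phi, SegmentationParams(minArea = a))$regions), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("border exclusion and hole filling are honoured", {
  pitch <- 1
  m <- matrix(FALSE, 100, 100)
  m[1:40, 1:40] <- TRUE       # touches the border
  m[60:90, 60:90] <- TRUE
  m[70:80, 70:80] <- FALSE    # hole
  sNo <- segmentCells(shapePhase(m, pitch),
                      SegmentationParams("fixed", fixedThreshold = 0.5,
                                         excludeBorder = TRUE))
  expect_identical(nrow(sNo$regions), 1L)
  expect_false(any(sNo$regions$touchesBorder))
  sFill <- segmentCells(shapePhase(m, pitch),
                        SegmentationParams("fixed", fixedThreshold = 0.5))
  expect_identical(nrow(sFill$regions), 2L)
  expect_true((31 * 31) %in% sFill$regions$areaUm2)  # hole filled
  sOpen <- segmentCells(shapePhase(m, pitch),
                        SegmentationParams("fixed", fixedThreshold = 0.5,
                                           fillHoles = FALSE))
  expect_true((31 * 31 - 11 * 11) %in% sOpen$regions$areaUm2)
})
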