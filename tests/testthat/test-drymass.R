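# Dry-mass formula, relative development, increments, aggregation and the
# significance stage.

test_that("uniform phase over the study FOV gives the hand-computed mass", {
  # dm = lambda/(2*pi*alpha) * 0.1 rad * (450 x 338 um) = 6778 pg
  qpi <- PhaseImage(matrix(0.1, 384, 512), pixelPitchUm = 450 / 512)
  expect_equal(dryMass(qpi), 0.532 / (2 * pi * 0.19) * 0.1 * 450 / 512 *
                 (450 / 512) * 384 * 512, tolerance = 1e-12)
  expect_equal(dryMass(qpi) / 1000, 6.78, tolerance = 0.005)
})

test_that("dry mass is linear in phase with an exact zero", {
  qpi0 <- PhaseImage(matrix(0, 128, 128), 0.88)
  expect_identical(dryMass(qpi0), 0)
  set.seed(3)
  ph <- matrix(runif(128 * 128, -0.2, 1), 128, 128)
  one <- dryMass(PhaseImage(ph, 0.88))
  expect_equal(dryMass(PhaseImage(2 * ph, 0.88)), 2 * one)
  # negative mean phase gives a negative mass
  expect_lt(dryMass(PhaseImage(matrix(-0.01, 128, 128), 0.88)), 0)
})

test_that("dry mass honours alpha, the cell mask and the validity mask", {
  ph <- matrix(0.1, 128, 128)
  qpi <- PhaseImage(ph, 0.88)
  expect_equal(dryMass(qpi, DryMassParams(alpha = 0.38)),
               dryMass(qpi) / 2)
  cellMask <- matrix(FALSE, 128, 128); cellMask[1:64, ] <- TRUE
  expect_equal(dryMass(qpi, cellMask = cellMask), dryMass(qpi) / 2)
  badMask <- matrix(FALSE, 128, 128); badMask[1:32, ] <- TRUE
  expect_error(dryMass(PhaseImage(ph, 0.88, badMask)), "invalid")
})

test_that("relative development subtracts (or divides by) the start value", {
  expect_equal(relativeDM(c(0, 6, 12), c(10, 11, 12)), c(0, 1, 2))
  expect_equal(relativeDM(c(0, 6, 12), c(7, 7, 7)), c(0, 0, 0))
  expect_equal(relativeDM(c(0, 12), c(10, 13), mode = "ratio"), c(1, 1.3))
  expect_error(relativeDM(c(1, 12), c(10, 13)), "t = 0")
})

test_that("the increment is the exact signed endpoint difference", {
  expect_equal(dryMassIncrement(c(0, 12), c(10e3, 13.2e3)), 3.2e3)
  expect_equal(dryMassIncrement(c(0, 12), c(5e3, 5e3)), 0)
  # negative increments are preserved (mass loss under lysis)
  expect_equal(dryMassIncrement(c(0, 12), c(12e3, 10.7e3)), -1.3e3)
  expect_error(dryMassIncrement(c(0, 6), c(1, 2), endTimeH = 12))
  # equals the relative development at the endpoint exactly
  dm <- c(10, 12, 9, 14) * 1e3
  expect_identical(dryMassIncrement(c(0, 4, 8, 12), dm),
                   relativeDM(c(0, 4, 8, 12), dm)[4])
})

test_that("condition aggregation reports mean, sample sd and pooled counts", {
  fs <- data.frame(
    condition = c("a", "a", "a", "b"), concentration = c(1, 1, 1, 2),
    dmiPg = c(1, 2, 3, 5), nRounded = c(1, 2, 0, 3),
    nTotal = c(10, 10, 5, 6))
  agg <- aggregateConditions(fs)
  a <- agg[agg$condition == "a", ]
  expect_equal(a$dmiMeanPg, 2)
  expect_equal(a$dmiSdPg, 1)
  expect_equal(a$roundedFraction, 3 / 25)
  b <- agg[agg$condition == "b", ]
  expect_true(is.na(b$dmiSdPg))  # single FOV: sd is missing
})

test_that("identical groups are not starred; separated groups are", {
  set.seed(5)
  fs <- data.frame(
    condition = rep(c("medium", "same", "far"), each = 9),
    experiment = rep(rep(1:3, each = 3), 3),
    dmiPg = c(rnorm(9, 3000, 300), rnorm(9, 3000, 300),
              rnorm(9, -2000, 300)))
  sig <- significanceVsControl(fs)
  expect_gt(sig$pValue[sig$condition == "same"], 0.05)
  expect_identical(sig$stars[sig$condition == "same"], "")
  expect_lt(sig$pValue[sig$condition == "far"], 0.005)
  expect_identical(sig$stars[sig$condition == "far"], "***")
})

test_that("the ANOVA stage holds its nominal type-I error rate", {
  set.seed(7)
  n <- 600
  hits <- 0L
  for (i in seq_len(n)) {
    fs <- data.frame(
      condition = rep(c("medium", "t"), each = 9),
      experiment = rep(rep(1:3, each = 3), 2),
      dmiPg = rnorm(18))
    p <- significanceVsControl(fs)$pValue
    hits <- hits + (p < 0.05)
  }
  expect_equal(hits / n, 0.05, tolerance = 0.5)  # 0.025..0.075
})
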