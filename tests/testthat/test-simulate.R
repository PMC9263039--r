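# Population simulator: growth, dose effects, manifest invariants,
# determinism.

test_that("medium control grows exponentially at the configured rate", {
  # deterministic mass growth: dm(12)/dm(0) = exp(0.06 * 12) exactly
  pop <- singleConditionPop(growthRate = 0.06, timepoints = c(0, 12),
                            nFOV = 3L, nExperiments = 1L)
  sim <- simulatePopulation(pop, tinyOptics(), seed = 11)
  ft <- fovTable(sim)
  for (v in 1:3) {
    r <- ft$truePopulationDryMassPg[ft$fov == v & ft$timeH == 12] /
      ft$truePopulationDryMassPg[ft$fov == v & ft$timeH == 0]
    expect_equal(r, exp(0.72), tolerance = 1e-10)
  }
})

test_that("saturating lysis leaves only sub-threshold debris", {
  dr <- data.frame(agent = "detergent",
                   effect = c("growth", "rounding", "lysis"),
                   ec50 = c(10, 10, 10), hill = c(2, 2, 2),
                   max = c(1, 0, 50))  # lysis rate so high every cell dies
  pop <- singleConditionPop("det", "detergent", 1000, doseResponse = dr,
                            susceptibilitySd = 1e-6,
                            timepoints = c(0, 12), nFOV = 2L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, tinyOptics(), seed = 4)
  cc <- cellTable(sim)
  at12 <- cc[cc$timeH == 12, ]
  expect_true(all(at12$state %in% c("removed", "debris")))
  frag <- at12[at12$state == "debris", ]
  expect_gt(nrow(frag), 0)
  expect_true(all(frag$supportAreaUm2 < 350))
  expect_true(all(frag$areaUm2 < 350))
  ft <- fovTable(sim)
  # population dry mass collapses to the debris-only mass
  expect_equal(ft$truePopulationDryMassPg[ft$timeH == 12],
               as.numeric(tapply(frag$dryMassPg, frag$fov, sum))[ft$fov[ft$timeH == 12]],
               tolerance = 1e-9)
  expect_lt(max(ft$truePopulationDryMassPg[ft$timeH == 12] /
                  ft$truePopulationDryMassPg[ft$timeH == 0]), 0.5)
})

test_that("zero treatment rounding leaves only the mitotic baseline", {
  pop <- singleConditionPop(baselineRoundingFraction = 0.1,
                            timepoints = 0:12, nFOV = 10L,
                            nExperiments = 1L)
  sim <- simulatePopulation(pop, tinyOptics(), seed = 21)
  cc <- cellTable(sim)
  intact <- cc[cc$state %in% c("spread", "rounded"), ]
  frac <- mean(intact$state == "rounded")
  expect_equal(frac, 0.1, tolerance = 0.035)
})

test_that("identical config and seed give bit-identical manifests", {
  pop <- PopulationConfig(nFOV = 1L, nExperiments = 1L, timepoints = c(0, 6))
  a <- simulatePopulation(pop, tinyOptics(), seed = 33)
  b <- simulatePopulation(pop, tinyOptics(), seed = 33)
  expect_identical(cellTable(a), cellTable(b))
  expect_identical(fovTable(a), fovTable(b))
  d <- simulatePopulation(pop, tinyOptics(), seed = 34)
  expect_false(identical(cellTable(a), cellTable(d)))
})

test_that("population dry mass equals the sum over non-removed cells", {
  pop <- PopulationConfig(conditions = data.frame(
    label = c("medium", "dig20"), agent = c("medium", "detergent"),
    concentration = c(0, 20)), nFOV = 2L, nExperiments = 1L,
    timepoints = c(0, 6, 12))
  sim <- simulatePopulation(pop, tinyOptics(), seed = 8)
  cc <- cellTable(sim); ft <- fovTable(sim)
  for (i in seq_len(nrow(ft))) {
    rows <- cc[cc$condition == ft$condition[i] & cc$fov == ft$fov[i] &
                 cc$timeH == ft$timeH[i] & cc$state != "removed", ]
    expect_equal(sum(rows$dryMassPg), ft$truePopulationDryMassPg[i])
  }
})

test_that("rounded cells are circular by construction, debris small", {
  pop <- PopulationConfig(conditions = data.frame(
    label = c("cbz", "dig"), agent = c("cytostatic", "detergent"),
    concentration = c(32, 140)), nFOV = 3L, nExperiments = 1L,
    timepoints = c(0, 12))
  sim <- simulatePopulation(pop, tinyOptics(), seed = 13)
  cc <- cellTable(sim)
  expect_true(all(cc$circularity[cc$state == "rounded"] > 0.8))
  expect_true(all(cc$supportAreaUm2[cc$state == "debris"] < 350))
})

test_that("expected 12-h dry mass is non-increasing in detergent dose", {
  pop <- PopulationConfig(conditions = data.frame(
    label = paste0("d", c(0.1, 5.5, 20, 140)),
    agent = "detergent", concentration = c(0.1, 5.5, 20, 140)),
    nFOV = 20L, nExperiments = 1L, timepoints = c(0, 12))
  sim <- simulatePopulation(pop, tinyOptics(), seed = 17)
  ft <- fovTable(sim)
  m12 <- tapply(ft$truePopulationDryMassPg[ft$timeH == 12],
                ft$concentration[ft$timeH == 12], mean)
  m12 <- m12[order(as.numeric(names(m12)))]
  expect_true(all(diff(m12) <= 0))
})
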