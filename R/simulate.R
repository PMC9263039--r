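## Stochastic population simulator: adherent epithelial cells that grow
## (medium control), round up (cytostatic response, mitosis) or lyse into
## sub-threshold debris (detergent response), in a concentration-dependent
## manner shaped by Hill dose-response curves.

.agentEffects <- function(pop, agent, concentration) {
  eff <- c(growth = 0, rounding = 0, lysis = 0)
  if (agent == "medium" || concentration <= 0) return(eff)
  dr <- pop@doseResponse[pop@doseResponse$agent == agent, , drop = FALSE]
  for (i in seq_len(nrow(dr))) {
    e <- hillEffect(concentration, dr$ec50[i], dr$hill[i]) * dr$max[i]
    eff[dr$effect[i]] <- e
  }
  eff
}

## one field of view: returns the long-format cell table (one row per
## entity per recorded time point)
.simulateFOV <- function(pop, optics, agent, concentration, subseed) {
  set.seed(subseed)
  W <- optics@fovWidthUm; H <- optics@fovHeightUm
  n0 <- pop@initialCellCount
  dt <- 1 # internal stepping (h)
  steps <- seq(0, max(pop@timepoints), by = dt)
  recorded <- pop@timepoints

  # per-cell static draws
  dm <- rlnorm(n0, log(pop@meanCellDryMass) - log(1 + pop@dryMassCV^2) / 2,
               sqrt(log(1 + pop@dryMassCV^2)))
  area <- pmax(700, rlnorm(n0, log(pop@meanSpreadArea) -
                             log(1 + pop@areaCV^2) / 2,
                           sqrt(log(1 + pop@areaCV^2))))
  ecc <- runif(n0, pop@spreadEccRange[1], pop@spreadEccRange[2])
  theta <- runif(n0, 0, pi)
  susc <- rlnorm(n0, -pop@susceptibilitySd^2 / 2, pop@susceptibilitySd)

  # sequential placement with a minimum centre distance; cells whose
  # support would cross the border are kept inside their own margin
  amax <- sqrt(area * ecc / pi)
  minDist <- 60
  x <- y <- numeric(n0)
  overlap <- logical(n0)
  for (i in seq_len(n0)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      xi <- runif(1, amax[i], W - amax[i])
      yi <- runif(1, amax[i], H - amax[i])
      if (i == 1L || min(sqrt((x[seq_len(i - 1)] - xi)^2 +
                              (y[seq_len(i - 1)] - yi)^2)) >= minDist) {
        placed <- TRUE; break
      }
    }
    x[i] <- xi; y[i] <- yi; overlap[i] <- !placed
  }

  eff <- .agentEffects(pop, agent, concentration)
  gEff <- pmin(1, eff["growth"] * susc)
  pRound <- 1 - exp(-eff["rounding"] * susc * dt)
  pLyse <- 1 - exp(-eff["lysis"] * susc * dt)
  # rounded (dying) cells rupture faster than spread cells
  pLyseRound <- 1 - exp(-eff["lysis"] * susc * pop@roundedLysisFactor * dt)

  roundedArea <- pmax(380, pop@roundedAreaFactor * area)
  roundedEcc <- runif(n0, 1.0, 1.1)

  state <- rep("spread", n0)  # permanent state of the original cells
  frag <- NULL                # data.frame of debris fragments
  nextId <- n0 + 1L
  rows <- vector("list", length(recorded))
  ri <- 0L

  for (t in steps) {
    if (t > 0) {
      alive <- which(state %in% c("spread", "rounded"))
      if (length(alive)) {
        u1 <- runif(length(alive))
        pl <- ifelse(state[alive] == "rounded", pLyseRound[alive],
                     pLyse[alive])
        lysed <- alive[u1 < pl]
        still <- setdiff(alive, lysed)
        sp <- still[state[still] == "spread"]
        if (length(sp)) {
          u2 <- runif(length(sp))
          state[sp[u2 < pRound[sp]]] <- "rounded"
        }
        # growth: spread, un-lysed cells only
        sp2 <- still[state[still] == "spread"]
        dm[sp2] <- dm[sp2] * exp(pop@growthRate * (1 - gEff[sp2]) * dt)
        for (i in lysed) {
          state[i] <- "removed"
          nf <- sample(2:4, 1)
          w <- runif(nf); w <- w / sum(w)
          kept <- runif(1, 0.25, 0.45)
          fa <- runif(nf, 60, 150)
          # fragments scatter on a ring so they stay resolvable
          ang <- 2 * pi * (seq_len(nf) - 1) / nf + runif(1, 0, 2 * pi)
          rad <- runif(nf, 18, 32)
          fx <- pmin(W - 10, pmax(10, x[i] + rad * cos(ang)))
          fy <- pmin(H - 10, pmax(10, y[i] + rad * sin(ang)))
          frag <- rbind(frag, data.frame(
            id = seq.int(nextId, length.out = nf), parent = i,
            dm = dm[i] * kept * w, area = fa,
            ecc = runif(nf, 1.1, 1.5), theta = runif(nf, 0, pi),
            x = fx, y = fy, born = t))
          nextId <- nextId + nf
        }
      }
    }
    if (t %in% recorded) {
      ri <- ri + 1L
      # transient mitotic rounding, redrawn at every recorded time point
      mit <- state == "spread" &
        runif(n0) < pop@baselineRoundingFraction
      showState <- state
      showState[mit] <- "rounded"
      isRound <- showState == "rounded"
      cellArea <- ifelse(isRound, roundedArea, area)
      cellEcc <- ifelse(isRound, roundedEcc, ecc)
      peak <- .peakPhase(dm, cellArea)
      cells <- data.frame(
        timeH = t, id = seq_len(n0), parent = NA_integer_,
        state = ifelse(state == "removed", "removed", showState),
        dryMassPg = ifelse(state == "removed", NA_real_, dm),
        xUm = x, yUm = y,
        supportAreaUm2 = ifelse(state == "removed", NA_real_, cellArea),
        areaUm2 = ifelse(state == "removed", NA_real_,
                         .thresholdArea(cellArea, peak)),
        ecc = cellEcc, theta = theta,
        circularity = ifelse(state == "removed", NA_real_,
                             .ellipseCircularity(cellEcc)),
        overlapPlaced = overlap)
      if (!is.null(frag)) {
        fr <- frag[frag$born <= t, , drop = FALSE]
        if (nrow(fr)) {
          fpeak <- .peakPhase(fr$dm, fr$area)
          cells <- rbind(cells, data.frame(
            timeH = t, id = fr$id, parent = fr$parent, state = "debris",
            dryMassPg = fr$dm, xUm = fr$x, yUm = fr$y,
            supportAreaUm2 = fr$area,
            areaUm2 = .thresholdArea(fr$area, fpeak),
            ecc = fr$ecc, theta = fr$theta,
            circularity = .ellipseCircularity(fr$ecc),
            overlapPlaced = FALSE))
        }
      }
      rows[[ri]] <- cells
    }
  }
  do.call(rbind, rows)
}

#' Simulate a time-lapse DHM assay population
#'
#' Runs the stochastic cell-population model for every experiment, condition
#' and field of view of the design in `pop`, producing a complete
#' ground-truth manifest.  Phase maps are not rasterized here; they are
#' rendered on demand by [truthPhase()] so arbitrarily large designs stay
#' cheap to simulate.
#'
#' Model summary: untreated spread cells grow exponentially in dry mass at
#' `growthRate`; a cytostatic agent converts spread cells to rounded
#' (dry mass conserved, footprint shrunk, peak phase raised) at a Hill-scaled
#' per-hour rate; a detergent lyses cells at a Hill-scaled rate into 2-4
#' debris fragments that retain 25-45% of the cell mass, each fragment below
#' the 350 um^2 debris threshold; every agent also inhibits growth via its
#' own Hill curve.  Per-cell lognormal susceptibility multiplies all agent
#' rates, so a concentration-dependent minority of resistant cells persists
#' at high doses.  A transient mitotic rounded fraction is redrawn at each
#' time point in all arms.
#'
#' @param pop a [PopulationConfig-class].
#' @param optics an [OpticsConfig-class].
#' @param seed integer master seed; every draw derives from it, so results
#'   are bit-reproducible.
#' @return a [SimulatedAssay-class].
#' @examples
#' pop <- PopulationConfig(conditions = data.frame(
#'   label = "medium", agent = "medium", concentration = 0),
#'   nFOV = 1L, nExperiments = 1L, timepoints = c(0, 12))
#' sim <- simulatePopulation(pop, OpticsConfig(sensorCols = 512,
#'   sensorRows = 384), seed = 1)
#' fovTable(sim)
#' @export
simulatePopulation <- function(pop, optics, seed = 1L) {
  validObject(pop); validObject(optics)
  seed <- as.integer(seed)
  conds <- pop@conditions
  out <- vector("list", pop@nExperiments * nrow(conds) * pop@nFOV)
  i <- 0L
  for (e in seq_len(pop@nExperiments)) {
    for (k in seq_len(nrow(conds))) {
      for (v in seq_len(pop@nFOV)) {
        tab <- .simulateFOV(pop, optics, conds$agent[k],
                            conds$concentration[k],
                            .subSeed(seed, e, k, v))
        i <- i + 1L
        out[[i]] <- cbind(data.frame(
          experiment = e, condition = conds$label[k],
          agent = conds$agent[k], concentration = conds$concentration[k],
          fov = v), tab)
      }
    }
  }
  cells <- do.call(rbind, out)
  rownames(cells) <- NULL

  key <- interaction(cells$experiment, cells$condition, cells$fov,
                     cells$timeH, drop = TRUE)
  counted <- !cells$state %in% "removed"
  intact <- cells$state %in% c("spread", "rounded")
  fov <- do.call(rbind, lapply(split(seq_len(nrow(cells)), key), function(ix) {
    cc <- cells[ix, ]
    nInt <- sum(intact[ix])
    data.frame(
      experiment = cc$experiment[1], condition = cc$condition[1],
      agent = cc$agent[1], concentration = cc$concentration[1],
      fov = cc$fov[1], timeH = cc$timeH[1],
      truePopulationDryMassPg = sum(cc$dryMassPg[counted[ix]], na.rm = TRUE),
      nCells = nInt,
      roundedFraction = if (nInt > 0)
        sum(cc$state[intact[ix]] == "rounded") / nInt else NA_real_)
  }))
  rownames(fov) <- NULL
  fov <- fov[order(fov$experiment, fov$condition, fov$fov, fov$timeH), ]

  new("SimulatedAssay", optics = optics, population = pop,
      truth = new("GroundTruth", cells = cells, fov = fov),
      seed = seed)
}

#' Ground-truth phase map of one simulated field of view
#'
#' Composes the phase footprints of all cells and debris fragments present
#' in the given FOV at the given time point onto the sensor raster.
#'
#' @param sim a [SimulatedAssay-class].
#' @param experiment,fov replicate indices.
#' @param condition condition label (as in the conditions table).
#' @param timeH recorded time point (h).
#' @param drymass a [DryMassParams-class] fixing the phase/mass conversion.
#' @return a [PhaseImage-class] of the true (noise-free) phase.
#' @export
truthPhase <- function(sim, experiment = 1L, condition, fov = 1L, timeH = 0,
                       drymass = DryMassParams()) {
  cc <- cellTable(sim)
  sel <- cc$experiment == experiment & cc$condition == condition &
    cc$fov == fov & cc$timeH == timeH & !cc$state %in% "removed"
  rows <- cc[sel, , drop = FALSE]
  opt <- sim@optics
  pitch <- pixelPitch(opt)
  nr <- opt@sensorRows; nc <- opt@sensorCols
  img <- matrix(0, nr, nc)
  for (i in seq_len(nrow(rows))) {
    st <- if (rows$state[i] == "debris") "rounded" else rows$state[i]
    patch <- cellPhaseFootprint(rows$dryMassPg[i], rows$supportAreaUm2[i],
                                rows$ecc[i], st, pitch, rows$theta[i],
                                alpha = drymass@alpha,
                                wavelengthUm = drymass@wavelengthUm)
    d <- dim(patch)
    r0 <- round(rows$yUm[i] / pitch) - (d[1] - 1L) %/% 2L
    c0 <- round(rows$xUm[i] / pitch) - (d[2] - 1L) %/% 2L
    rr <- seq.int(r0, length.out = d[1])
    cs <- seq.int(c0, length.out = d[2])
    keepR <- rr >= 1L & rr <= nr
    keepC <- cs >= 1L & cs <= nc
    img[rr[keepR], cs[keepC]] <- img[rr[keepR], cs[keepC]] +
      patch[keepR, keepC, drop = FALSE]
  }
  PhaseImage(img, pitch,
             meta = list(experiment = experiment, condition = condition,
                         fov = fov, timeH = timeH, truth = TRUE))
}
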