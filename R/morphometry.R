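## Threshold-based single-cell segmentation and circularity morphometry.

#' Circularity of a segmented region
#'
#' \code{C = 4*pi*area/perimeter^2}: 1 for an ideal circle, pi/4 (~0.785)
#' for a square, decreasing with elongation.  Estimator overshoot above 1 is
#' clipped.
#'
#' @param area region area (um^2), > 0; vectorized.
#' @param perimeter region perimeter (um), > 0.
#' @return circularity in (0, 1].
#' @examples
#' circularity(pi * 20^2, 2 * pi * 20)  # 1
#' circularity(100, 40)                 # square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  pmin(1, 4 * pi * area / perimeter^2)
}

#' Segment cells in a quantitative phase image
#'
#' Binary mask by phase thresholding (automatic Otsu threshold with a noise
#' floor, or a fixed threshold), hole filling, 8-connected labelling, and a
#' debris size filter \code{S_cell > minArea}.  Region perimeters come from
#' a smoothed crack-boundary polygon (convergent for discs of growing
#' radius); circularity is computed per region and clipped to 1.
#'
#' @param qpi a background-compensated [PhaseImage-class].
#' @param params a [SegmentationParams-class].
#' @param drymass a [DryMassParams-class] for per-region dry mass.
#' @return list with `labels` (integer label map; regions failing the size
#'   filter are zeroed) and `regions` (data.frame: label, areaUm2,
#'   perimeterUm, circularity, meanPhaseRad, dryMassPg, xUm, yUm,
#'   touchesBorder).
#' @export
segmentCells <- function(qpi, params = SegmentationParams(),
                         drymass = DryMassParams()) {
  validObject(params)
  ph <- phaseArray(qpi)
  mask <- validMask(qpi)
  pitch <- pixelPitch(qpi)
  work <- ph
  work[!mask] <- 0

  thr <- if (params@thresholdMethod == "fixed") {
    params@fixedThreshold
  } else {
    rng <- range(work[mask])
    if (diff(rng) <= 0) {
      params@thresholdFloor
    } else {
      sc <- (work - rng[1]) / diff(rng)
      sc[sc < 0] <- 0; sc[sc > 1] <- 1
      t01 <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
      max(rng[1] + t01 * diff(rng), params@thresholdFloor)
    }
  }

  bin <- work > thr & mask
  if (!any(bin)) {
    return(list(labels = matrix(0L, nrow(ph), ncol(ph)),
                regions = .emptyRegions()))
  }
  if (params@fillHoles) {
    bin <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bin * 1))) > 0.5
  }
  lab <- .label_components8(bin)
  nlab <- max(lab)
  pix <- tabulate(lab[lab > 0L], nbins = nlab)
  areas <- pix * pitch^2
  perims <- .crack_perimeters(lab, nlab, params@smoothWindow) * pitch

  idx <- which(lab > 0L)
  labf <- factor(lab[idx], levels = seq_len(nlab))
  sumPhase <- as.numeric(tapply(ph[idx], labf, sum))
  nr <- nrow(ph); nc <- ncol(ph)
  rows0 <- (idx - 1L) %% nr
  cols0 <- (idx - 1L) %/% nr
  cx <- as.numeric(tapply(cols0, labf, mean)) * pitch
  cy <- as.numeric(tapply(rows0, labf, mean)) * pitch
  touch <- as.logical(tapply(rows0 == 0L | rows0 == nr - 1L |
                               cols0 == 0L | cols0 == nc - 1L, labf, any))

  keep <- areas > params@minArea
  if (params@excludeBorder) keep <- keep & !touch
  regions <- data.frame(
    label = seq_len(nlab),
    areaUm2 = areas,
    perimeterUm = perims,
    circularity = circularity(pmax(areas, 1e-12), pmax(perims, 1e-12)),
    meanPhaseRad = sumPhase / pix,
    dryMassPg = drymass@wavelengthUm / (2 * pi * drymass@alpha) *
      sumPhase * pitch^2,
    xUm = cx, yUm = cy,
    touchesBorder = touch)[keep, , drop = FALSE]
  rownames(regions) <- NULL
  lab[!(lab %in% regions$label)] <- 0L
  list(labels = lab, regions = regions)
}

.emptyRegions <- function() {
  data.frame(label = integer(), areaUm2 = numeric(), perimeterUm = numeric(),
             circularity = numeric(), meanPhaseRad = numeric(),
             dryMassPg = numeric(), xUm = numeric(), yUm = numeric(),
             touchesBorder = logical())
}

#' Fraction of rounded cells
#'
#' Number of segmented cells with circularity above the threshold divided by
#' the total number of segmented cells.  An empty region list yields a
#' missing fraction (flagged), never 0.
#'
#' @param regions region table from [segmentCells()] (already size-filtered).
#' @param cRound circularity threshold (default 0.8).
#' @return list with `fraction` (NA when undefined), `nRounded`, `nTotal`
#'   and `undefined`.
#' @export
roundedFraction <- function(regions, cRound = 0.8) {
  n <- nrow(regions)
  if (n == 0L)
    return(list(fraction = NA_real_, nRounded = 0L, nTotal = 0L,
                undefined = TRUE))
  k <- sum(regions$circularity > cRound)
  list(fraction = k / n, nRounded = k, nTotal = n, undefined = FALSE)
}
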