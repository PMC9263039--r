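## Single-cell phase footprints and dose-response shaping.

## flat-top elliptical profile with a C1 cosine taper over the outer
## `taper` fraction of the normalized radius
.TAPER <- 0.8

## relative integral of the profile over the unit-area support ellipse:
## s^2 + w*[(s + w/2) - 2*w/pi^2] with s = 1 - w
.profileIntegralFactor <- function(taper = .TAPER) {
  s <- 1 - taper; w <- taper
  s^2 + w * ((s + w / 2) - 2 * w / pi^2)
}

## profile height at normalized elliptical radius r (peak 1)
.profileShape <- function(r, taper = .TAPER) {
  s <- 1 - taper
  out <- r * 0
  out[r <= s] <- 1
  mid <- r > s & r < 1
  out[mid] <- 0.5 * (1 + cos(pi * (r[mid] - s) / taper))
  out
}

## normalized radius at which the profile crosses `ratio` (of the peak);
## NA when the level is above the peak
.profileCrossRadius <- function(ratio, taper = .TAPER) {
  s <- 1 - taper
  out <- rep(NA_real_, length(ratio))
  out[ratio <= 0] <- 1
  ok <- ratio > 0 & ratio < 1
  out[ok] <- s + taper * acos(2 * ratio[ok] - 1) / pi
  out[ratio >= 1] <- NA_real_
  out
}

#' Hill dose-response effect
#'
#' Fractional effect \code{c^h / (c^h + ec50^h)}, monotone nondecreasing in
#' the concentration, used to scale growth inhibition, rounding and lysis
#' rates with agent concentration.
#'
#' @param concentration agent concentration (ug/mL), >= 0; vectorized.
#' @param ec50 half-maximal concentration (ug/mL), > 0.
#' @param hill Hill coefficient, > 0.
#' @return effect fraction in [0, 1].
#' @examples
#' hillEffect(10, ec50 = 10, hill = 2)   # 0.5 at the EC50
#' hillEffect(100, ec50 = 10, hill = 2)  # ~0.99
#' @export
hillEffect <- function(concentration, ec50, hill) {
  stopifnot(ec50 > 0, hill > 0, all(concentration >= 0))
  ch <- (concentration / ec50)^hill
  ch / (ch + 1)
}

#' Render the phase footprint of one cell
#'
#' Rasterizes a smooth elliptical phase patch whose integrated optical path
#' encodes exactly the requested dry mass: the patch is rescaled after
#' rasterization so that \code{sum(phase) * pitch^2 * lambda/(2*pi*alpha)}
#' equals \code{dryMassPg}.  Spread cells are elongated flat-top blobs,
#' rounded cells near-circular blobs of the same mass on a smaller footprint
#' (hence higher peak phase), and debris is rendered as three small
#' fragments sharing the requested mass and area.
#'
#' @param dryMassPg cell dry mass (pg), > 0 (0 gives an all-zero patch).
#' @param areaUm2 support-ellipse area (um^2).
#' @param eccentricity axis ratio a/b >= 1.
#' @param state one of "spread", "rounded", "debris".
#' @param pixelPitchUm raster pitch (um).
#' @param theta major-axis orientation (rad).
#' @param profile "flattop" (default) or "disc" (uniform phase over the
#'   ellipse, useful for analytic checks: peak = 2*pi*alpha*dm/(lambda*area)).
#' @param alpha,wavelengthUm dry-mass formula constants (um^3/pg, um).
#' @return numeric matrix (rad), non-negative, odd dimensions, cell centred.
#' @examples
#' p <- cellPhaseFootprint(300, 600, 1, "rounded", 0.44)
#' sum(p) * 0.44^2 * 0.532 / (2 * pi * 0.19)  # = 300 pg
#' @export
cellPhaseFootprint <- function(dryMassPg, areaUm2, eccentricity = 1,
                               state = c("spread", "rounded", "debris"),
                               pixelPitchUm, theta = 0,
                               profile = c("flattop", "disc"),
                               alpha = 0.19, wavelengthUm = 0.532) {
  state <- match.arg(state)
  profile <- match.arg(profile)
  stopifnot(dryMassPg >= 0, eccentricity >= 1, pixelPitchUm > 0)
  pixArea <- pixelPitchUm^2
  if (areaUm2 < 4 * pixArea)
    stop("footprint area smaller than 4 pixels cannot be rasterized")
  if (dryMassPg == 0) return(matrix(0, 1L, 1L))

  targetV <- dryMassPg * 2 * pi * alpha / wavelengthUm  # um^2 * rad

  if (state == "debris") {
    # three fragments, fixed mass/area split, arranged around the centre
    fm <- c(0.5, 0.3, 0.2)
    sub <- lapply(seq_along(fm), function(i)
      cellPhaseFootprint(dryMassPg * fm[i], areaUm2 * fm[i], 1.3, "rounded",
                         pixelPitchUm, theta = i, profile = profile,
                         alpha = alpha, wavelengthUm = wavelengthUm))
    spread <- sqrt(areaUm2) * 1.2 / pixelPitchUm
    offs <- rbind(c(-0.5, -0.4), c(0.55, -0.1), c(-0.05, 0.6)) * spread
    half <- ceiling(max(vapply(sub, function(m) max(dim(m)), 0)) / 2 +
                      max(abs(offs))) + 1L
    n <- 2L * half + 1L
    patch <- matrix(0, n, n)
    for (i in seq_along(sub)) {
      d <- dim(sub[[i]])
      r0 <- half + 1L + round(offs[i, 1]) - (d[1] - 1L) %/% 2L
      c0 <- half + 1L + round(offs[i, 2]) - (d[2] - 1L) %/% 2L
      patch[r0:(r0 + d[1] - 1L), c0:(c0 + d[2] - 1L)] <-
        patch[r0:(r0 + d[1] - 1L), c0:(c0 + d[2] - 1L)] + sub[[i]]
    }
    return(patch)
  }

  a <- sqrt(areaUm2 * eccentricity / pi)   # semi-major (um)
  b <- sqrt(areaUm2 / (pi * eccentricity)) # semi-minor (um)
  half <- ceiling(a / pixelPitchUm) + 1L
  n <- 2L * half + 1L
  u <- (seq_len(n) - half - 1L) * pixelPitchUm
  X <- matrix(u, n, n, byrow = TRUE)
  Y <- matrix(u, n, n)
  Xr <- cos(theta) * X + sin(theta) * Y
  Yr <- -sin(theta) * X + cos(theta) * Y
  r <- sqrt((Xr / a)^2 + (Yr / b)^2)
  patch <- if (profile == "disc") (r <= 1) * 1.0 else .profileShape(r)
  s <- sum(patch) * pixArea
  if (s <= 0) return(matrix(0, n, n))
  patch <- patch * (targetV / s)
  if (max(patch) > 4 * pi)
    warning("peak phase exceeds 4*pi rad; unwrapping will be stressed")
  patch
}

## circularity of an ellipse with axis ratio q >= 1 (Ramanujan perimeter)
.ellipseCircularity <- function(q) {
  h <- ((q - 1) / (q + 1))^2
  P <- pi * (q + 1) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * (pi * q) / P^2
}

## area (um^2) of the region where the cell phase exceeds `floorRad`,
## given the peak phase of the rasterized footprint
.thresholdArea <- function(supportAreaUm2, peakPhase, floorRad = 0.15) {
  ratio <- floorRad / peakPhase
  r <- .profileCrossRadius(ratio)
  ifelse(is.na(r), 0, r^2 * supportAreaUm2)
}

## peak phase of the flat-top footprint for mass/area bookkeeping
.peakPhase <- function(dryMassPg, supportAreaUm2,
                       alpha = 0.19, wavelengthUm = 0.532) {
  dryMassPg * 2 * pi * alpha / wavelengthUm /
    (supportAreaUm2 * .profileIntegralFactor())
}
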