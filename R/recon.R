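## Fourier-transform reconstruction of off-axis holograms: carrier
## location, sideband demodulation, angular-spectrum propagation and
## autofocus.

## 2D Tukey (tapered-cosine) apodization window, cached per geometry
.tukey1 <- function(n, alpha = 0.1) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

.tukey2d <- function(nr, nc, alpha = 0.1) {
  key <- paste("tk", nr, nc, alpha, sep = "_")
  w <- .gridCache[[key]]
  if (is.null(w)) {
    w <- outer(.tukey1(nr, alpha), .tukey1(nc, alpha))
    .gridCache[[key]] <- w
  }
  w
}

## valid-pixel mask excluding the apodized border
.borderMask <- function(nr, nc, alpha = 0.1) {
  .tukey2d(nr, nc, alpha) > 0.1
}

#' Locate the off-axis carrier frequency in a hologram spectrum
#'
#' Finds the spectral peak of maximal magnitude outside a DC exclusion disc
#' of radius 10% of the Nyquist frequency, refines it to sub-bin accuracy by
#' log-parabolic interpolation, and resolves the conjugate ambiguity by
#' returning the peak in the half-plane with positive x-frequency (ties:
#' positive y).
#'
#' @param holo a [Hologram-class].
#' @return carrier frequency, cycles/um, length 2 (x, y).
#' @export
locateCarrier <- function(holo) {
  I <- intensityArray(holo)
  nr <- nrow(I); nc <- ncol(I)
  pitch <- pixelPitch(holo)
  FT <- stats::fft(I * .tukey2d(nr, nc))
  mag <- Mod(FT)
  g <- .freqGrids(nr, nc, pitch)
  nyq <- 1 / (2 * pitch)
  rho <- sqrt(g$FX^2 + g$FY^2)
  outside <- rho >= 0.1 * nyq
  m <- mag
  m[!outside] <- 0
  peak <- which.max(m)
  if (m[peak] < 3 * median(mag[outside]) || m[peak] < 0.05 * mag[1])
    stop("no carrier: no spectral peak above 3x the median magnitude")
  pi_ <- (peak - 1) %% nr          # 0-based row
  pj_ <- (peak - 1) %/% nr         # 0-based col
  # sub-bin refinement on log magnitude along each axis (cyclic neighbours)
  refine <- function(im, i0, n) {
    a <- log(im[(i0 - 1) %% n + 1] + 1e-300)
    b <- log(im[i0 + 1] + 1e-300)
    cc <- log(im[(i0 + 1) %% n + 1] + 1e-300)
    den <- a - 2 * b + cc
    if (abs(den) < 1e-12) 0 else 0.5 * (a - cc) / den
  }
  di <- refine(mag[, pj_ + 1], pi_, nr)
  dj <- refine(mag[pi_ + 1, ], pj_, nc)
  tofreq <- function(idx, d, n) {
    k <- idx + d
    if (k > n / 2) k <- k - n
    k / n
  }
  f <- c(tofreq(pj_, dj, nc) / pitch, tofreq(pi_, di, nr) / pitch)
  if (f[1] < 0 || (f[1] == 0 && f[2] < 0)) f <- -f
  f
}

#' Reconstruct the complex object wave by Fourier sideband demodulation
#'
#' The hologram is apodized (10% Tukey border window), demodulated by the
#' carrier, low-pass filtered with a raised-cosine circular window and
#' inverse-transformed, yielding the complex object wave sampled on the
#' original grid.
#'
#' @param holo a [Hologram-class].
#' @param carrier carrier frequency (cycles/um, length 2); NULL to locate it
#'   with [locateCarrier()].
#' @param filterRadius spatial-frequency radius of the sideband filter
#'   (cycles/um); default 0.4 x |carrier|.  The raised-cosine edge spans the
#'   outer 20% of the radius.
#' @return a [ComplexField-class].
#' @export
reconstructFourier <- function(holo, carrier = NULL, filterRadius = NULL) {
  I <- intensityArray(holo)
  nr <- nrow(I); nc <- ncol(I)
  pitch <- pixelPitch(holo)
  if (is.null(carrier)) carrier <- locateCarrier(holo)
  fmag <- sqrt(sum(carrier^2))
  if (is.null(filterRadius)) filterRadius <- 0.4 * fmag
  nyq <- 1 / (2 * pitch)
  if (filterRadius <= 0 || fmag - filterRadius < 0.1 * nyq)
    stop("sideband filter overlaps the DC exclusion disc")
  g <- .xyGrids(nr, nc, pitch)
  key <- paste("dm", nr, nc, signif(pitch, 12),
               signif(carrier[1], 12), signif(carrier[2], 12), sep = "_")
  dem <- .gridCache[[key]]
  if (is.null(dem)) {
    dem <- exp(-2i * pi * (carrier[1] * g$X + carrier[2] * g$Y))
    .gridCache[[key]] <- dem
  }
  wkey <- paste("lp", nr, nc, signif(pitch, 12), signif(filterRadius, 12),
                sep = "_")
  W <- .gridCache[[wkey]]
  if (is.null(W)) {
    fg <- .freqGrids(nr, nc, pitch)
    rho <- sqrt(fg$FX^2 + fg$FY^2)
    inner <- 0.8 * filterRadius
    W <- matrix(0, nr, nc)
    W[rho <= inner] <- 1
    edge <- rho > inner & rho < filterRadius
    W[edge] <- 0.5 * (1 + cos(pi * (rho[edge] - inner) / (0.2 * filterRadius)))
    .gridCache[[wkey]] <- W
  }
  FT <- stats::fft(I * .tukey2d(nr, nc) * dem)
  fld <- stats::fft(FT * W, inverse = TRUE) / length(FT)
  ComplexField(fld, pitch, holo@wavelengthNm)
}

#' Angular-spectrum free-space propagation
#'
#' Exact scalar propagation of the complex field over `distanceUm` along the
#' optical axis; evanescent components are suppressed.  Total power is
#' conserved for propagating components.
#'
#' @param field a [ComplexField-class].
#' @param distanceUm propagation distance (um); may be negative.
#' @return a [ComplexField-class].
#' @export
propagateField <- function(field, distanceUm) {
  if (distanceUm == 0) return(field)
  F <- fieldArray(field)
  nr <- nrow(F); nc <- ncol(F)
  pitch <- pixelPitch(field)
  lam <- field@wavelengthNm / 1000
  g <- .freqGrids(nr, nc, pitch)
  arg <- 1 / lam^2 - g$FX^2 - g$FY^2
  H <- matrix(0i, nr, nc)
  prop <- arg > 0
  H[prop] <- exp(2i * pi * distanceUm * sqrt(arg[prop]))
  out <- stats::fft(stats::fft(F) * H, inverse = TRUE) / length(F)
  ComplexField(out, pitch, field@wavelengthNm)
}

## amplitude variance on the central region (the apodized border diffracts
## on propagation and would otherwise dominate): for a phase object the
## amplitude contrast -- and with it the variance -- is minimal in focus and
## grows symmetrically with defocus
.focusCost <- function(F) {
  nr <- nrow(F); nc <- ncol(F)
  A <- Mod(F[round(nr * 0.15):round(nr * 0.85),
             round(nc * 0.15):round(nc * 0.85)])
  stats::var(as.vector(A))
}

#' Autofocus by amplitude contrast
#'
#' Propagates the field over a grid of candidate distances and returns the
#' distance minimizing the variance of the amplitude (phase objects show
#' minimal amplitude contrast in focus), refined by parabolic interpolation
#' around the grid minimum.
#'
#' @param field a [ComplexField-class].
#' @param searchRange length-2 distance interval (um).
#' @param stepUm grid step (um).
#' @return focus distance (um); 0 with a warning when the cost landscape is
#'   flat (relative variation below 1e-3).
#' @export
autofocus <- function(field, searchRange = c(-100, 100), stepUm = 5) {
  d <- seq(searchRange[1], searchRange[2], by = stepUm)
  cost <- vapply(d, function(z) .focusCost(fieldArray(
    propagateField(field, z))), 0)
  if ((max(cost) - min(cost)) / max(max(cost), 1e-300) < 1e-3) {
    warning("autofocus cost landscape is flat; returning 0")
    return(0)
  }
  i <- which.min(cost)
  if (i == 1L || i == length(d)) return(d[i])
  a <- cost[i - 1]; b <- cost[i]; cc <- cost[i + 1]
  den <- a - 2 * b + cc
  d[i] + if (abs(den) < 1e-12) 0 else 0.5 * (a - cc) / den * stepUm
}

#' Reconstruct an averaged, compensated QPI from a hologram series
#'
#' The computation behind each time point of the assay: every frame of the
#' 7-frame series is demodulated ([reconstructFourier()]), optionally
#' refocused, unwrapped ([unwrapPhase()]) and background-compensated
#' ([compensateBackground()]); the compensated frames are then averaged
#' ([averagePhase()]) to suppress the frame-decorrelated coherence-induced
#' disturbances.
#'
#' @param holos list of [Hologram-class] (>= 2 frames, identical geometry).
#' @param carrier carrier frequency or NULL (located on the first frame).
#' @param filterRadius sideband filter radius (cycles/um) or NULL.
#' @param refocus "off", "auto", or a numeric distance in um.
#' @param polyOrder background polynomial order.
#' @return a [PhaseImage-class].
#' @export
reconstructSeries <- function(holos, carrier = NULL, filterRadius = NULL,
                              refocus = "off", polyOrder = 2L) {
  stopifnot(length(holos) >= 2L)
  if (is.null(carrier)) carrier <- locateCarrier(holos[[1]])
  dist <- 0
  frames <- vector("list", length(holos))
  for (i in seq_along(holos)) {
    fld <- reconstructFourier(holos[[i]], carrier, filterRadius)
    if (i == 1L && identical(refocus, "auto")) dist <- autofocus(fld)
    else if (is.numeric(refocus)) dist <- refocus
    if (dist != 0) fld <- propagateField(fld, dist)
    F <- fieldArray(fld)
    mask <- .borderMask(nrow(F), ncol(F))
    wrapped <- Arg(F)
    un <- unwrapPhase(wrapped, mask)
    frames[[i]] <- PhaseImage(un, pixelPitch(fld), mask)
  }
  # piston-normalized average first, full surface compensation once on the
  # averaged image: the background/cell classification is ill-posed on
  # single frames where the parasitic interference dominates the residual
  # scale, and the polynomial fit commutes with the average
  out <- compensateBackground(averagePhase(frames), polyOrder = polyOrder)
  out@meta <- c(holos[[1]]@meta, list(refocusUm = dist))
  out
}
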