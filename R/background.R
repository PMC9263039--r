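## Background normalization of reconstructed phase images and averaging of
## the 7-frame series.

## polynomial basis x^i y^j (i + j <= order) on [-1, 1] coordinates,
## evaluated at the given 0-based pixel indices
.polyBasis <- function(rows, cols, nr, nc, order) {
  xn <- 2 * cols / (nc - 1) - 1
  yn <- 2 * rows / (nr - 1) - 1
  terms <- list()
  for (i in 0:order) for (j in 0:(order - i))
    terms[[length(terms) + 1L]] <- xn^i * yn^j
  do.call(cbind, terms)
}

#' Background compensation of a phase image
#'
#' Iteratively fits a 2D polynomial surface to background pixels and
#' subtracts it: starting from all valid pixels, three rounds of fit /
#' subtract / robust re-classification (background = |residual| < 3 robust
#' sigma) converge on the aberration surface while excluding cell regions.
#' The residual background median is removed, so reported phases follow the
#' convention background median = 0.  If fewer than 20% of pixels classify
#' as background, the border frame is used instead (with a warning).
#'
#' @param phase a [PhaseImage-class] or numeric matrix (rad).
#' @param polyOrder polynomial surface order (default 2).
#' @param pixelPitchUm pixel pitch when `phase` is a bare matrix.
#' @param maxFitPixels subsample cap for the least-squares fit.
#' @return a [PhaseImage-class] with flattened background.
#' @export
compensateBackground <- function(phase, polyOrder = 2L, pixelPitchUm = NULL,
                                 maxFitPixels = 20000L) {
  if (is(phase, "PhaseImage")) {
    qpi <- phase
    ph <- phaseArray(qpi); mask <- validMask(qpi)
    pitch <- pixelPitch(qpi); meta <- qpi@meta
  } else {
    ph <- phase
    mask <- matrix(TRUE, nrow(ph), ncol(ph))
    pitch <- if (is.null(pixelPitchUm)) 1 else pixelPitchUm
    meta <- list()
  }
  nr <- nrow(ph); nc <- ncol(ph)
  valid <- which(mask)
  # regular subsample of valid pixels for the fit
  stride <- max(1L, floor(length(valid) / maxFitPixels))
  fitIdx <- valid[seq(1L, length(valid), by = stride)]
  rows0 <- (fitIdx - 1L) %% nr
  cols0 <- (fitIdx - 1L) %/% nr
  B <- .polyBasis(rows0, cols0, nr, nc, polyOrder)
  z <- ph[fitIdx]
  bg <- rep(TRUE, length(fitIdx))
  coef <- NULL
  for (it in 1:5) {
    if (sum(bg) < ncol(B) + 2L) break
    coef <- stats::lm.fit(B[bg, , drop = FALSE], z[bg])$coefficients
    coef[is.na(coef)] <- 0
    resid <- z - drop(B %*% coef)
    # cells only push the phase up, so the noise scale is estimated from
    # the negative flank of the residual distribution; this keeps faint
    # cell tails out of the background class
    rb <- resid[bg]
    neg <- rb[rb < stats::median(rb)]
    sigma <- 1.4826 * stats::median(stats::median(rb) - neg)
    if (!is.finite(sigma) || sigma <= 0) sigma <- stats::mad(rb)
    if (!is.finite(sigma) || sigma <= 0) break
    bg <- abs(resid) < 3 * sigma
  }
  if (mean(bg) < 0.20) {
    warning("background fraction below 20%; falling back to border-frame pixels")
    border <- rows0 < 0.05 * nr | rows0 > 0.95 * nr |
      cols0 < 0.05 * nc | cols0 > 0.95 * nc
    if (sum(border) >= ncol(B) + 2L) {
      coef <- stats::lm.fit(B[border, , drop = FALSE], z[border])$coefficients
      coef[is.na(coef)] <- 0
      bg <- border
    }
  }
  if (is.null(coef)) coef <- c(stats::median(z), numeric(ncol(B) - 1L))
  # evaluate the surface on the full grid
  allRows <- (seq_len(nr * nc) - 1L) %% nr
  allCols <- (seq_len(nr * nc) - 1L) %/% nr
  surf <- matrix(drop(.polyBasis(allRows, allCols, nr, nc, polyOrder) %*% coef),
                 nr, nc)
  out <- ph - surf
  piston <- stats::median(out[fitIdx][bg])
  out <- out - piston
  PhaseImage(out, pitch, mask, meta = meta)
}

#' Average a series of compensated phase images
#'
#' Removes the per-frame piston (median over valid pixels) and takes the
#' pixelwise mean over the frames in which each pixel is valid, reducing
#' frame-decorrelated disturbances by about 1/sqrt(n).
#'
#' @param frames list of [PhaseImage-class] with identical geometry (>= 2).
#' @return a [PhaseImage-class]; pixels valid in no frame are masked out.
#' @export
averagePhase <- function(frames) {
  stopifnot(length(frames) >= 2L)
  d <- dim(phaseArray(frames[[1]]))
  pitch <- pixelPitch(frames[[1]])
  for (f in frames) {
    if (!all(dim(phaseArray(f)) == d) ||
        abs(pixelPitch(f) - pitch) > 1e-9 * pitch)
      stop("frame geometry mismatch")
  }
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (f in frames) {
    ph <- phaseArray(f); m <- validMask(f)
    piston <- stats::median(ph[m])
    acc[m] <- acc[m] + (ph[m] - piston)
    cnt[m] <- cnt[m] + 1L
  }
  ok <- cnt > 0L
  out <- matrix(0, d[1], d[2])
  out[ok] <- acc[ok] / cnt[ok]
  PhaseImage(out, pitch, ok, meta = frames[[1]]@meta)
}
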