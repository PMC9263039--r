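## Population dry-mass analytics: whole-field dry mass from the mean phase
## shift, relative dry-mass development, 12-h increments, replicate
## aggregation and the significance stage.

#' Whole-field cellular dry mass from a phase image
#'
#' \code{dm = lambda/(2*pi*alpha) * mean(phase) * S_FOV}, where the mean
#' phase shift is taken over all valid pixels of the background-compensated
#' image and S_FOV is the geometric field-of-view area.  The result is
#' linear in phase and may be negative (background fluctuation).
#'
#' @param qpi a background-compensated [PhaseImage-class].
#' @param params a [DryMassParams-class].
#' @param cellMask optional logical matrix restricting the phase integral to
#'   segmented cell regions (sensitivity variant; the default follows the
#'   whole-field convention).
#' @return dry mass in pg.
#' @examples
#' ph <- PhaseImage(matrix(0.1, 384, 512), pixelPitchUm = 450 / 512)
#' dryMass(ph) / 1000  # ng
#' @export
dryMass <- function(qpi, params = DryMassParams(), cellMask = NULL) {
  mask <- validMask(qpi)
  if (mean(mask) < 0.5)
    stop("more than 50% of pixels are invalid; refusing to extrapolate")
  ph <- phaseArray(qpi)
  if (!is.null(cellMask)) {
    sel <- mask & cellMask
    tot <- sum(ph[sel]) * pixelPitch(qpi)^2
    return(params@wavelengthUm / (2 * pi * params@alpha) * tot)
  }
  # masked-out border pixels follow the background-zero convention, so the
  # mean phase shift is the valid-pixel sum over the full pixel count;
  # this keeps the phase integral (and hence dm) free of the mask geometry
  dphi <- sum(ph[mask]) / length(ph)
  params@wavelengthUm / (2 * pi * params@alpha) * dphi * fovArea(qpi)
}

#' Relative dry-mass development with respect to t = 0
#'
#' Default convention: subtraction, \code{DM(t) = dm(t) - dm(0)} (units
#' preserved, consistent with increments reported in ng); a ratio mode
#' \code{dm(t)/dm(0)} is available.
#'
#' @param timesH time points (h); must include 0.
#' @param dmPg dry mass per time point (pg).
#' @param mode "subtract" (default) or "ratio".
#' @return numeric vector of DM values, same order as `timesH`.
#' @export
relativeDM <- function(timesH, dmPg, mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(length(timesH) == length(dmPg))
  i0 <- which(timesH == 0)
  if (length(i0) != 1L) stop("t = 0 is required for normalization")
  if (mode == "subtract") dmPg - dmPg[i0] else dmPg / dmPg[i0]
}

#' Dry-mass increment between assay start and endpoint
#'
#' \code{DMI = dm(t_end) - dm(t_0)}; by the subtraction convention this
#' equals DM at the endpoint exactly.
#'
#' @param timesH time points (h).
#' @param dmPg dry mass per time point (pg).
#' @param endTimeH endpoint (default: the latest time present).
#' @return increment in pg (sign preserved).
#' @export
dryMassIncrement <- function(timesH, dmPg, endTimeH = max(timesH)) {
  i0 <- which(timesH == 0)
  i1 <- which(timesH == endTimeH)
  if (length(i0) != 1L || length(i1) != 1L)
    stop("both endpoints (0 and ", endTimeH, " h) are required")
  dmPg[i1] - dmPg[i0]
}

#' Aggregate per-FOV endpoints by condition
#'
#' Mean and sample standard deviation (n - 1 denominator) of the dry-mass
#' increment over the FOVs of each condition, plus the pooled rounded
#' fraction (total rounded / total cells across FOVs).
#'
#' @param fovSummary data.frame with columns condition, concentration,
#'   dmiPg, nRounded, nTotal (one row per FOV).
#' @return data.frame, one row per condition.
#' @export
aggregateConditions <- function(fovSummary) {
  sp <- split(fovSummary, fovSummary$condition)
  out <- do.call(rbind, lapply(sp, function(g) {
    n <- sum(is.finite(g$dmiPg))
    data.frame(
      condition = g$condition[1],
      concentration = g$concentration[1],
      nFOV = n,
      dmiMeanPg = mean(g$dmiPg, na.rm = TRUE),
      dmiSdPg = if (n >= 2L) sd(g$dmiPg, na.rm = TRUE) else NA_real_,
      nRounded = sum(g$nRounded, na.rm = TRUE),
      nTotal = sum(g$nTotal, na.rm = TRUE),
      roundedFraction = if (sum(g$nTotal, na.rm = TRUE) > 0)
        sum(g$nRounded, na.rm = TRUE) / sum(g$nTotal, na.rm = TRUE)
      else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(match(out$condition, unique(fovSummary$condition))), ]
}

.stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.005, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Significance of condition effects versus the medium control
#'
#' For each treated condition, a two-factor analysis of variance of the
#' per-FOV dry-mass increments on the subset {condition, control}, with
#' factors group and experiment (`aov(dmi ~ group + experiment)`), gives the
#' p-value for the group factor.  Stars follow the three-level convention
#' p < 0.005 (***), p < 0.01 (**), p < 0.05 (*).
#'
#' @param fovSummary data.frame with columns condition, experiment, dmiPg.
#' @param control label of the medium control (default "medium").
#' @return data.frame: condition, pValue, stars.
#' @export
significanceVsControl <- function(fovSummary, control = "medium") {
  conds <- setdiff(unique(fovSummary$condition), control)
  ctrl <- fovSummary[fovSummary$condition == control, , drop = FALSE]
  out <- do.call(rbind, lapply(conds, function(cd) {
    g <- fovSummary[fovSummary$condition == cd, , drop = FALSE]
    p <- NA_real_
    if (nrow(g) >= 2L && nrow(ctrl) >= 2L) {
      d <- rbind(
        data.frame(dmi = ctrl$dmiPg, group = "control",
                   experiment = factor(ctrl$experiment)),
        data.frame(dmi = g$dmiPg, group = "treated",
                   experiment = factor(g$experiment)))
      d <- d[is.finite(d$dmi), , drop = FALSE]
      if (length(unique(d$group)) == 2L && stats::var(d$dmi) > 0) {
        form <- if (nlevels(droplevels(d$experiment)) > 1L)
          dmi ~ group + experiment else dmi ~ group
        fit <- try(stats::aov(form, data = d), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          tab <- summary(fit)[[1]]
          p <- tab[["Pr(>F)"]][rownames(tab) == "group      "]
          if (length(p) == 0)
            p <- tab[["Pr(>F)"]][trimws(rownames(tab)) == "group"]
          p <- p[1]
        }
      } else {
        warning("degenerate variance for condition ", cd, "; p set to NA")
      }
    }
    data.frame(condition = cd, pValue = p, stars = .stars(p))
  }))
  rownames(out) <- NULL
  out
}
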