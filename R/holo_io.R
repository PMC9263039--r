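## Hologram and phase-image I/O: multi-page TIFF with a YAML sidecar that
## records pixel geometry, wavelength, intensity scaling and page order.

#' Write a hologram stack as multi-page TIFF
#'
#' Pages are ordered time-major, then frame 0..6.  Intensities are stored as
#' 16-bit unsigned after a fixed linear scaling recorded in the sidecar YAML
#' (`<file>.yaml`), which also carries pixel pitch, wavelength and the page
#' table.
#'
#' @param holos list of [Hologram-class] objects (time-major, frame-minor).
#' @param file output TIFF path.
#' @return invisibly, the sidecar path.
#' @export
writeHologramStack <- function(holos, file) {
  stopifnot(length(holos) > 0)
  scaleMax <- max(vapply(holos, function(h) max(h@intensity), 0))
  if (scaleMax <= 0) scaleMax <- 1
  pages <- lapply(holos, function(h) h@intensity / scaleMax)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L, compression = "none")
  side <- paste0(file, ".yaml")
  meta <- list(
    pixel_pitch_um = holos[[1]]@pixelPitchUm,
    wavelength_nm = holos[[1]]@wavelengthNm,
    scale_max = scaleMax,
    pages = lapply(holos, function(h) {
      m <- h@meta
      list(timeH = if (is.null(m$timeH)) NA else m$timeH,
           frame = if (is.null(m$frame)) NA else m$frame)
    }))
  yaml::write_yaml(meta, side)
  invisible(side)
}

#' Read a hologram stack written by [writeHologramStack()]
#'
#' Any multi-page TIFF can be read as long as a sidecar YAML with
#' `pixel_pitch_um`, `wavelength_nm`, `scale_max` and a `pages` table sits
#' next to it.
#'
#' @param file TIFF path.
#' @return list of [Hologram-class] objects.
#' @export
readHologramStack <- function(file) {
  side <- paste0(file, ".yaml")
  if (!file.exists(side)) stop("sidecar YAML not found: ", side)
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(file, all = TRUE)
  lapply(seq_along(pages), function(i) {
    pm <- if (i <= length(meta$pages)) meta$pages[[i]] else list()
    Hologram(pages[[i]] * meta$scale_max, meta$pixel_pitch_um,
             meta$wavelength_nm, meta = pm)
  })
}

#' Write a phase image (32-bit float TIFF + mask)
#'
#' @param qpi a [PhaseImage-class].
#' @param file output TIFF path; the mask goes to `<file>.mask.tif` and the
#'   pixel geometry to `<file>.yaml`.
#' @return invisibly, `file`.
#' @export
writePhaseImage <- function(qpi, file) {
  ph <- phaseArray(qpi)
  rng <- range(ph)
  if (diff(rng) <= 0) rng[2] <- rng[1] + 1
  tiff::writeTIFF((ph - rng[1]) / diff(rng), file, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  tiff::writeTIFF(1 * validMask(qpi), paste0(file, ".mask.tif"),
                  bits.per.sample = 8L, compression = "none")
  yaml::write_yaml(list(pixel_pitch_um = qpi@pixelPitchUm,
                        phase_min = rng[1], phase_max = rng[2]),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' Read a phase image written by [writePhaseImage()]
#' @param file TIFF path.
#' @return a [PhaseImage-class].
#' @export
readPhaseImage <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  ph <- tiff::readTIFF(file)
  if (!is.null(meta$phase_min))
    ph <- ph * (meta$phase_max - meta$phase_min) + meta$phase_min
  mfile <- paste0(file, ".mask.tif")
  mask <- if (file.exists(mfile)) tiff::readTIFF(mfile) > 0.5 else NULL
  PhaseImage(ph, meta$pixel_pitch_um, mask)
}

#' Write the 96-well plate layout of a design
#'
#' One row per condition x experiment x FOV with a synthetic well id,
#' mirroring a plate map (well, condition, agent, concentration).
#'
#' @param pop a [PopulationConfig-class].
#' @param file CSV path.
#' @return invisibly, the layout data.frame.
#' @export
writePlateLayout <- function(pop, file) {
  conds <- pop@conditions
  rows <- LETTERS[1:8]
  out <- do.call(rbind, lapply(seq_len(nrow(conds)), function(k) {
    do.call(rbind, lapply(seq_len(pop@nFOV), function(v) {
      idx <- (k - 1) * pop@nFOV + v - 1
      data.frame(well = paste0(rows[idx %% 8 + 1], idx %/% 8 + 1),
                 condition = conds$label[k], agent = conds$agent[k],
                 concentration = conds$concentration[k], fov = v)
    }))
  }))
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}
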