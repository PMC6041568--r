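#' Raw sensor frames for radiometric calibration
#'
#' Bundles the target digital numbers (DN) with the dark-current and
#' white-panel reference frames needed to convert counts to reflectance:
#' `Ref_target = (DN_target - DN_noise) / (DN_panel - DN_noise) * Ref_panel`.
#' Dark current is treated as a per-band vector, consistent with a pushbroom
#' sensor whose electronic offset varies with the spectral channel.
#'
#' @param dn_target numeric 3-D array of target counts (rows x cols x bands).
#' @param dn_noise dark-current counts per band (scalar recycled).
#' @param dn_panel white-panel counts per band.
#' @param ref_panel panel reflectance in `(0, 1]`.
#' @param wavelength band wavelengths, nm.
#' @param pixel_size_mm ground pixel size, mm.
#' @param meta metadata list carried through to the calibrated cube.
#' @return object of class `calibration_frames`.
#' @export
calibration_frames <- function(dn_target, dn_noise, dn_panel, ref_panel = 0.99,
                               wavelength, pixel_size_mm = 1.3, meta = list()) {
  if (is.matrix(dn_target)) dim(dn_target) <- c(dim(dn_target), 1L)
  stopifnot(is.array(dn_target), length(dim(dn_target)) == 3L)
  nb <- dim(dn_target)[3]
  dn_noise <- rep_len(as.numeric(dn_noise), nb)
  dn_panel <- rep_len(as.numeric(dn_panel), nb)
  if (ref_panel <= 0 || ref_panel > 1) stop("Ref_panel must lie in (0, 1]")
  if (length(wavelength) != nb) stop("wavelength length must match band count")
  structure(list(dn_target = dn_target, dn_noise = dn_noise,
                 dn_panel = dn_panel, ref_panel = as.numeric(ref_panel),
                 wavelength = as.numeric(wavelength),
                 pixel_size_mm = pixel_size_mm, meta = meta),
            class = "calibration_frames")
}

#' Radiometric calibration from digital numbers to reflectance
#'
#' Applies, per pixel and band,
#' `Ref_target = (DN_target - DN_noise) / (DN_panel - DN_noise) * Ref_panel`.
#' `DN_target = DN_panel` recovers the panel reflectance and
#' `DN_target = DN_noise` gives zero.
#'
#' @param frames a [calibration_frames()] object.
#' @return a [spectral_cube()] of relative reflectance.
#' @export
calibrate_reflectance <- function(frames) {
  stopifnot(inherits(frames, "calibration_frames"))
  denom <- frames$dn_panel - frames$dn_noise
  bad <- which(denom == 0)
  if (length(bad))
    stop("DN_panel equals DN_noise at band ", bad[1], " (",
         frames$wavelength[bad[1]], " nm): calibration denominator is zero")
  d <- dim(frames$dn_target)
  dn <- matrix(frames$dn_target, d[1] * d[2], d[3])
  refl <- sweep(sweep(dn, 2L, frames$dn_noise, `-`), 2L,
                frames$ref_panel / denom, `*`)
  spectral_cube(array(refl, dim = d), frames$wavelength,
                pixel_size_mm = frames$pixel_size_mm, meta = frames$meta)
}

#' Subset a cube to a wavelength window
#'
#' Retains bands with `lo_nm <= wavelength <= hi_nm`, preserving order. The
#' standard preprocessing window is 400-900 nm, outside of which pushbroom
#' VNIR data are too noisy to use.
#'
#' @param cube a [spectral_cube()].
#' @param lo_nm,hi_nm window bounds in nm.
#' @return a [spectral_cube()] with the retained bands.
#' @export
subset_spectral <- function(cube, lo_nm = 400, hi_nm = 900) {
  stopifnot(inherits(cube, "spectral_cube"))
  keep <- cube$wavelength >= lo_nm & cube$wavelength <= hi_nm
  if (!any(keep))
    stop("no bands in [", lo_nm, ", ", hi_nm, "] nm (axis spans ",
         min(cube$wavelength), "-", max(cube$wavelength), " nm)")
  spectral_cube(cube$data[, , keep, drop = FALSE], cube$wavelength[keep],
                pixel_size_mm = cube$pixel_size_mm, meta = cube$meta)
}
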