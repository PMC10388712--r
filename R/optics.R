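#' Acquisition metadata for the holographic microscope
#'
#' Bundles the optical constants needed to convert pixel measurements into
#' physical units. The effective object-plane sampling is
#' `pixel_pitch / magnification` micrometres per pixel.
#'
#' @param wavelength Illumination wavelength in nanometres.
#' @param pixel_pitch Detector pixel pitch in micrometres.
#' @param magnification Lateral magnification of the imaging objective.
#' @param numerical_aperture Objective numerical aperture, in (0, 1].
#'
#' @return An object of class `optics_meta`.
#' @examples
#' optics_meta()
#' @export
optics_meta <- function(wavelength = 650,
                        pixel_pitch = 5.86,
                        magnification = 40,
                        numerical_aperture = 0.75) {
  stopifnot(
    is.numeric(wavelength), length(wavelength) == 1, wavelength > 0,
    is.numeric(pixel_pitch), length(pixel_pitch) == 1, pixel_pitch > 0,
    is.numeric(magnification), length(magnification) == 1, magnification > 0,
    is.numeric(numerical_aperture), length(numerical_aperture) == 1
  )
  if (numerical_aperture <= 0 || numerical_aperture > 1) {
    stop("`numerical_aperture` must lie in (0, 1].", call. = FALSE)
  }
  structure(
    list(
      wavelength = wavelength,
      pixel_pitch = pixel_pitch,
      magnification = magnification,
      numerical_aperture = numerical_aperture
    ),
    class = "optics_meta"
  )
}

#' @export
print.optics_meta <- function(x, ...) {
  cat(sprintf(
    "<optics_meta> lambda = %g nm, pitch = %g um, mag = %gx, NA = %g\n",
    x$wavelength, x$pixel_pitch, x$magnification, x$numerical_aperture
  ))
  cat(sprintf("  object-plane sampling: %.4f um/px\n", pixel_size_um(x)))
  invisible(x)
}

#' Object-plane pixel size in micrometres
#'
#' @param meta An [optics_meta()] object.
#' @return Micrometres per pixel at the sample plane.
#' @export
pixel_size_um <- function(meta) {
  stopifnot(inherits(meta, "optics_meta"))
  meta$pixel_pitch / meta$magnification
}
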