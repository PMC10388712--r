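#' Tilted plane reference wave
#'
#' In off-axis holography the reference beam hits the detector at a small
#' angle, which shows up as a linear phase ramp: a spatial carrier with a
#' fixed fringe frequency. The carrier moves the object information away from
#' the DC term in the Fourier domain so that a single shot encodes the full
#' complex field.
#'
#' @param shape Image size `c(rows, cols)`.
#' @param tilt Carrier frequency `c(f_row, f_col)` in cycles per pixel; each
#'   component must be strictly below Nyquist (|f| < 0.5).
#' @param amplitude Reference amplitude (> 0), flat across the field.
#'
#' @return An object of class `reference_wave` with elements `tilt`,
#'   `amplitude`, `shape` and `values` (complex matrix
#'   `amplitude * exp(2i*pi*(f_row*row + f_col*col))`, 0-based coordinates).
#' @examples
#' R <- make_reference(c(64, 64), tilt = c(0.125, 0.125))
#' Mod(R$values[1, 1])
#' @export
make_reference <- function(shape, tilt = c(0.125, 0.125), amplitude = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 2), length(tilt) == 2)
  if (any(abs(tilt) >= 0.5)) {
    stop("Reference tilt must be below Nyquist (|f| < 0.5 cycles/px).",
         call. = FALSE)
  }
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("`amplitude` must be > 0.", call. = FALSE)
  }
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  values <- amplitude * exp(2i * pi * (tilt[1] * rr + tilt[2] * cc))
  structure(
    list(tilt = as.numeric(tilt), amplitude = as.numeric(amplitude),
         shape = shape, values = values),
    class = "reference_wave"
  )
}

#' @export
print.reference_wave <- function(x, ...) {
  cat(sprintf("<reference_wave> tilt = (%.4g, %.4g) cycles/px, amplitude = %g, %d x %d\n",
              x$tilt[1], x$tilt[2], x$amplitude, x$shape[1], x$shape[2]))
  invisible(x)
}

#' Complex optical field container
#'
#' Thin wrapper around a complex matrix tagging its role in the imaging
#' model: the object wave, the reference wave, or a numerical reconstruction.
#'
#' @param values Complex (or numeric) matrix with finite entries.
#' @param role One of `"object"`, `"reference"`, `"reconstruction"`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, role = c("object", "reference", "reconstruction")) {
  role <- match.arg(role)
  stopifnot(is.matrix(values))
  values <- matrix(as.complex(values), nrow(values), ncol(values))
  if (!all(is.finite(Re(values)) & is.finite(Im(values)))) {
    stop("`values` must be finite.", call. = FALSE)
  }
  structure(list(values = values, role = role), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> role = %s, %d x %d, mean |.| = %.4g\n",
              x$role, nrow(x$values), ncol(x$values), mean(Mod(x$values))))
  invisible(x)
}

# Accept either a reference_wave or a complex_field/matrix as reference values.
reference_values <- function(reference) {
  if (inherits(reference, "reference_wave")) return(reference$values)
  if (inherits(reference, "complex_field")) return(reference$values)
  if (is.matrix(reference)) return(reference)
  stop("`reference` must be a reference_wave, complex_field or matrix.",
       call. = FALSE)
}
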