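#' Render an off-axis hologram from a phase object
#'
#' Applies the interference model for image-plane holography: the detector
#' records `H = |O + R|^2` where `O = a * exp(i * phase)` is the in-focus
#' object wave and `R` the tilted plane reference. Expanding the modulus
#' gives the usual four terms `|O|^2 + |R|^2 + O R* + O* R`; the last two
#' carry the complex field on the tilt carrier. Detector noise is modelled
#' as additive zero-mean Gaussian on the intensity, clipped at zero.
#'
#' @param phase Phase of the object wave: a `phase_map`, a `pollen_phantom`
#'   (its `true_phase` is used) or a plain matrix of radians.
#' @param reference A [make_reference()] wave of matching shape.
#' @param object_amplitude Object-wave amplitude: scalar or matrix. Defaults
#'   to 1 everywhere (pure-phase object; the acetocarmine stain absorbs
#'   negligibly at 650 nm, so absorption is off by default).
#' @param noise_sd Standard deviation of additive intensity noise (counts).
#' @param seed Optional integer seed for the noise draw.
#' @param meta [optics_meta()] to attach to the hologram.
#'
#' @return An object of class `hologram`: list with `values` (real matrix,
#'   intensity), `meta`, `noise_sd`.
#' @examples
#' ph <- make_phantom("viable", shape = c(64, 64), center = c(32, 32),
#'                    radius = 20, peak_phase = 6)
#' R <- make_reference(c(64, 64))
#' H <- forward_hologram(ph, R)
#' min(H$values) >= 0
#' @export
forward_hologram <- function(phase, reference, object_amplitude = 1,
                             noise_sd = 0, seed = NULL,
                             meta = optics_meta()) {
  phi <- phase_values(phase)
  Rv <- reference_values(reference)
  if (!all(dim(phi) == dim(Rv))) {
    stop("Phase and reference shapes disagree.", call. = FALSE)
  }
  if (is.matrix(object_amplitude) && !all(dim(object_amplitude) == dim(phi))) {
    stop("`object_amplitude` shape disagrees with the phase.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)

  O <- object_amplitude * exp(1i * phi)
  H <- Mod(O + Rv)^2
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    H <- H + matrix(stats::rnorm(length(H), sd = noise_sd), nrow(H), ncol(H))
    H <- pmax(H, 0)
  }
  structure(list(values = H, meta = meta, noise_sd = noise_sd),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d, intensity range [%.4g, %.4g], noise sd = %g\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              x$noise_sd))
  invisible(x)
}

# Extract a plain phase matrix from the containers that can carry one.
phase_values <- function(phase) {
  if (inherits(phase, "phase_map")) return(phase$values)
  if (inherits(phase, "pollen_phantom")) return(phase$true_phase)
  if (is.matrix(phase)) return(phase)
  stop("`phase` must be a phase_map, pollen_phantom or matrix.", call. = FALSE)
}

hologram_values <- function(hologram) {
  if (inherits(hologram, "hologram")) return(hologram$values)
  if (is.matrix(hologram)) return(hologram)
  stop("`hologram` must be a hologram or matrix.", call. = FALSE)
}
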