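#' Synthetic pollen phantom with known ground-truth phase
#'
#' Builds a single pollen phantom on a pixel grid: a binary support disk and a
#' ground-truth phase surface in radians. Viable grains carry a nearly
#' hemispherical phase dome (cytoplasm-filled grain acting as a plano-convex
#' phase object); non-viable grains carry a nearly flat interior plateau with
#' a thin raised rim, mimicking an emptied grain whose wall still delays the
#' beam. An optional smoothed zero-mean texture emulates intracellular
#' granularity.
#'
#' @param label `"viable"` or `"nonviable"`.
#' @param shape Image size as `c(rows, cols)`.
#' @param center Disk centre `c(row, col)`, 0-based pixel coordinates.
#' @param radius Disk radius in pixels (>= 3).
#' @param peak_phase Peak phase in radians. For viable grains this is the dome
#'   apex; for non-viable grains it is the rim (wall) height and the interior
#'   plateau sits at `plateau_frac * peak_phase`.
#' @param texture_sd Standard deviation (radians) of the smoothed intracellular
#'   texture added inside the support; 0 disables it.
#' @param seed Optional integer seed for the texture noise.
#' @param profile Phase profile override: `"auto"` (hemisphere for viable, rim
#'   for non-viable), `"hemisphere"`, `"rim"`, or `"cylinder"` (sharp-edged
#'   top-hat, useful for resolution experiments).
#' @param plateau_frac Interior plateau height of the rim profile, as a
#'   fraction of `peak_phase`.
#'
#' @return An object of class `pollen_phantom`: a list with `label`, `center`,
#'   `radius`, `peak_phase`, `rim_phase`, `true_phase` (matrix, radians) and
#'   `true_mask` (logical matrix).
#'
#' @details For the hemispherical profile the phase at radial coordinate `r`
#' is `peak_phase * sqrt(1 - (r/radius)^2)`; its analytic mean over the
#' support disk is `(2/3) * peak_phase`, which the population generator uses
#' to hit a target mean phase.
#'
#' @examples
#' ph <- make_phantom("viable", shape = c(64, 64), center = c(32, 32),
#'                    radius = 20, peak_phase = 6)
#' mean(ph$true_phase[ph$true_mask])  # ~ 4 = (2/3) * 6
#' @export
make_phantom <- function(label = c("viable", "nonviable"),
                         shape = c(256, 256),
                         center = (shape - 1) / 2,
                         radius = 40,
                         peak_phase = 9,
                         texture_sd = 0,
                         seed = NULL,
                         profile = c("auto", "hemisphere", "rim", "cylinder"),
                         plateau_frac = 0.75) {
  label <- match.arg(label)
  profile <- match.arg(profile)
  if (profile == "auto") {
    profile <- if (label == "viable") "hemisphere" else "rim"
  }
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 8), length(center) == 2)
  if (!is.numeric(radius) || radius < 3) {
    stop("`radius` must be a number >= 3 pixels.", call. = FALSE)
  }
  if (!is.numeric(peak_phase) || peak_phase < 0) {
    stop("`peak_phase` must be >= 0.", call. = FALSE)
  }
  if (texture_sd < 0) stop("`texture_sd` must be >= 0.", call. = FALSE)
  if (center[1] - radius < 0 || center[1] + radius > shape[1] - 1 ||
      center[2] - radius < 0 || center[2] + radius > shape[2] - 1) {
    stop("Phantom disk does not fit inside the image bounds.", call. = FALSE)
  }

  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  rho <- sqrt((rr - center[1])^2 + (cc - center[2])^2) / radius
  mask <- rho <= 1

  unit <- switch(profile,
    hemisphere = {
      u <- sqrt(pmax(1 - rho^2, 0))
      u[!mask] <- 0
      u
    },
    rim = {
      # Wall band spans the outer quarter of the radius: at the samplings
      # this package emulates that is several pixels wide, matching a real
      # exine wall rather than a one-pixel cliff.
      bump <- ifelse(rho >= 0.75 & rho <= 1,
                     cos(pi * (rho - 0.875) / 0.25)^2, 0)
      plateau <- ifelse(rho <= 0.875, plateau_frac, 0)
      u <- pmax(plateau, bump)
      u[!mask] <- 0
      u
    },
    cylinder = {
      u <- matrix(0, shape[1], shape[2])
      u[mask] <- 1
      u
    }
  )
  phase <- peak_phase * unit

  if (texture_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    noise <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    smooth <- Re(gaussian_blur_fft(noise, sigma = 2))
    envelope <- unit / max(unit)
    tex <- smooth * envelope
    inside <- mask & envelope > 0
    s <- stats::sd(tex[inside])
    if (s > 0) tex <- tex * (texture_sd / s)
    phase <- pmax(phase + tex * mask, 0)
  }

  structure(
    list(
      label = label,
      center = as.numeric(center),
      radius = as.numeric(radius),
      peak_phase = as.numeric(peak_phase),
      rim_phase = if (profile == "rim") as.numeric(peak_phase) else 0,
      profile = profile,
      true_phase = phase,
      true_mask = mask
    ),
    class = "pollen_phantom"
  )
}

#' @export
print.pollen_phantom <- function(x, ...) {
  cat(sprintf(
    "<pollen_phantom> %s (%s), r = %g px, peak = %.3g rad, mask mean = %.3g rad\n",
    x$label, x$profile, x$radius, x$peak_phase, phantom_mean_phase(x)
  ))
  invisible(x)
}

#' Mask-mean ground-truth phase of a phantom
#'
#' @param phantom A [make_phantom()] object.
#' @return Mean of `true_phase` over `true_mask`, radians.
#' @export
phantom_mean_phase <- function(phantom) {
  stopifnot(inherits(phantom, "pollen_phantom"))
  mean(phantom$true_phase[phantom$true_mask])
}

# Periodic Gaussian blur via FFT; adequate for interior texture fields.
gaussian_blur_fft <- function(x, sigma) {
  n <- dim(x)
  fr <- c(0:(floor(n[1] / 2)), -((ceiling(n[1] / 2) - 1):1)) / n[1]
  fc <- c(0:(floor(n[2] / 2)), -((ceiling(n[2] / 2) - 1):1)) / n[2]
  H <- outer(exp(-2 * pi^2 * sigma^2 * fr^2), exp(-2 * pi^2 * sigma^2 * fc^2))
  stats::fft(stats::fft(x) * H, inverse = TRUE) / prod(n)
}
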