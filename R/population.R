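#' Simulate a population of pollen holograms with known ground truth
#'
#' Draws a two-class population of pollen phantoms and renders one off-axis
#' hologram per grain. Each grain gets a viability label (Bernoulli with
#' `viable_fraction`), a target mean phase drawn from its class normal
#' distribution, a radius and a centre position; the phantom's peak phase is
#' set so that its mask-mean phase equals the target (for the hemispherical
#' dome the analytic rule `peak = 1.5 * target` is used; for the rim profile
#' the unit-profile mean is computed numerically and scaled). The defaults
#' mirror the study conditions this pipeline is designed around: 508 grains
#' in nearly equal proportion with class mean-phase centres 8.72 (viable)
#' and 4.26 (non-viable) radians.
#'
#' @param n Number of grains (>= 1).
#' @param viable_fraction Probability that a grain is viable.
#' @param mean_phase_centers Class centres of the mean-phase distribution,
#'   `c(viable, nonviable)`, radians.
#' @param mean_phase_sd Within-class standard deviation of the target mean
#'   phase, radians.
#' @param shape Per-grain region-of-interest size `c(rows, cols)`.
#' @param radius_range Uniform range for the grain radius, pixels.
#' @param tilt Reference carrier frequency, cycles/pixel.
#' @param ref_amplitude Reference wave amplitude.
#' @param texture_sd Intracellular texture standard deviation, radians.
#' @param noise_sd Additive intensity noise standard deviation, counts.
#' @param seed Master seed; the whole population is reproducible from it and
#'   each grain additionally records its own derived seed.
#' @param meta [optics_meta()] attached to every hologram.
#'
#' @return A tibble of class `pollen_population`, one row per grain, with
#'   columns `id`, `label`, `center_row`, `center_col`, `radius`,
#'   `peak_phase`, `target_mean_phase`, `seed` and list-columns `phantom`
#'   and `hologram`. The reference wave and optics metadata are attached as
#'   attributes `reference` and `meta`.
#' @examples
#' pop <- generate_population(n = 4, shape = c(64, 64),
#'                            radius_range = c(12, 18), seed = 1)
#' pop$label
#' @export
generate_population <- function(n = 508,
                                viable_fraction = 0.5,
                                mean_phase_centers = c(8.72, 4.26),
                                mean_phase_sd = 0.8,
                                shape = c(192, 192),
                                radius_range = c(66, 78),
                                tilt = c(0.25, 0.25),
                                ref_amplitude = 1,
                                texture_sd = 0.15,
                                noise_sd = 0.05,
                                seed = 1,
                                meta = optics_meta()) {
  if (!is.numeric(n) || n < 1) {
    stop("Empty population: `n` must be >= 1.", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(viable_fraction >= 0, viable_fraction <= 1,
            length(mean_phase_centers) == 2, mean_phase_sd >= 0,
            length(radius_range) == 2, radius_range[1] >= 3)
  shape <- as.integer(shape)
  margin <- ceiling(radius_range[2]) + 2
  if (any(shape < 2 * margin + 4)) {
    stop("`shape` too small for the requested `radius_range`.", call. = FALSE)
  }

  set.seed(as.integer(seed))
  label <- ifelse(stats::runif(n) < viable_fraction, "viable", "nonviable")
  center_mu <- ifelse(label == "viable",
                      mean_phase_centers[1], mean_phase_centers[2])
  target <- pmax(0.2, stats::rnorm(n, mean = center_mu, sd = mean_phase_sd))
  radius <- stats::runif(n, radius_range[1], radius_range[2])
  c_row <- stats::runif(n, margin, shape[1] - 1 - margin)
  c_col <- stats::runif(n, margin, shape[2] - 1 - margin)
  grain_seed <- sample.int(.Machine$integer.max - 1L, 2 * n)
  tex_seed <- grain_seed[seq_len(n)]
  noi_seed <- grain_seed[n + seq_len(n)]

  reference <- make_reference(shape, tilt = tilt, amplitude = ref_amplitude)

  build_one <- function(i) {
    if (label[i] == "viable") {
      peak <- 1.5 * target[i]
      ph <- make_phantom("viable", shape = shape,
                         center = c(c_row[i], c_col[i]), radius = radius[i],
                         peak_phase = peak, texture_sd = texture_sd,
                         seed = tex_seed[i])
    } else {
      unit <- make_phantom("nonviable", shape = shape,
                           center = c(c_row[i], c_col[i]), radius = radius[i],
                           peak_phase = 1, texture_sd = 0)
      peak <- target[i] / phantom_mean_phase(unit)
      ph <- make_phantom("nonviable", shape = shape,
                         center = c(c_row[i], c_col[i]), radius = radius[i],
                         peak_phase = peak, texture_sd = texture_sd,
                         seed = tex_seed[i])
    }
    H <- forward_hologram(ph, reference, noise_sd = noise_sd,
                          seed = noi_seed[i], meta = meta)
    list(phantom = ph, hologram = H, peak = peak)
  }
  built <- lapply(seq_len(n), build_one)

  out <- tibble::tibble(
    id = sprintf("pollen_%04d", seq_len(n)),
    label = label,
    center_row = c_row,
    center_col = c_col,
    radius = radius,
    peak_phase = vapply(built, function(b) b$peak, numeric(1)),
    target_mean_phase = target,
    seed = tex_seed,
    noise_seed = noi_seed,
    phantom = lapply(built, `[[`, "phantom"),
    hologram = lapply(built, `[[`, "hologram")
  )
  attr(out, "reference") <- reference
  attr(out, "meta") <- meta
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("pollen_population", class(out))
  out
}

#' Population manifest without image payloads
#'
#' Drops the list-columns so the ground truth can be written as a plain CSV.
#'
#' @param population A [generate_population()] tibble.
#' @return A tibble of the scalar ground-truth columns.
#' @export
population_manifest <- function(population) {
  stopifnot(inherits(population, "pollen_population"))
  tibble::as_tibble(population[, c("id", "label", "center_row", "center_col",
                                   "radius", "peak_phase",
                                   "target_mean_phase", "seed")])
}
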