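pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    save_images = FALSE,
    optics = list(wavelength = 650, pixel_pitch = 5.86, magnification = 40,
                  numerical_aperture = 0.75),
    simulate = list(n = 508L, viable_fraction = 0.5,
                    mean_phase_centers = c(8.72, 4.26), mean_phase_sd = 0.8,
                    shape = c(192L, 192L), radius_range = c(66, 78),
                    tilt = c(0.25, 0.25), ref_amplitude = 1,
                    texture_sd = 0.15, noise_sd = 0.05),
    reconstruct = list(method = "sparse", reference = "known",
                       filter_radius = NULL,
                       epsilon = 1e-9, max_iters = 150,
                       rel_change_tol = 1e-4, step_init = 0.05,
                       balance_ratio = 0.5, init_mode = "fourier"),
    segment = list(min_area = 64, threshold_mode = "otsu",
                   threshold = NULL, floor_frac = 0.12),
    classify = list(band_halfwidth = NULL, gmm_seed = NULL)
  )
}

merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("Unknown ", path, " key(s): ",
         paste0("`", unknown, "`", collapse = ", "), ".", call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     path = paste0(path, "$", nm))
    } else {
      # single-bracket assignment keeps keys whose new value is NULL
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

#' Configuration for the end-to-end pipeline
#'
#' Builds a validated pipeline configuration from named overrides of the
#' defaults (see [pipeline_defaults printed by `print()`][run_pipeline]).
#' Unknown keys are rejected so typos fail before any stage runs; the whole
#' object serialises to a single YAML document.
#'
#' @param ... Named overrides, possibly nested lists (e.g.
#'   `simulate = list(n = 20)`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(pipeline_defaults(), user)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$reconstruct$max_iters < 1) {
    stop("Invalid config: `reconstruct$max_iters` must be >= 1.",
         call. = FALSE)
  }
  if (!cfg$reconstruct$method %in% c("sparse", "fourier")) {
    stop("Invalid config: `reconstruct$method` must be \"sparse\" or ",
         "\"fourier\".", call. = FALSE)
  }
  if (!cfg$reconstruct$reference %in% c("known", "estimate")) {
    stop("Invalid config: `reconstruct$reference` must be \"known\" or ",
         "\"estimate\".", call. = FALSE)
  }
  if (cfg$simulate$n < 1) {
    stop("Invalid config: `simulate$n` must be >= 1.", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML document of overrides.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(pipeline_config, user)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# Deterministic fan-out of the master seed to per-stage seeds:
# seed_stage = (master * 48271 + 1000003 * stage_index) mod (2^31 - 1).
stage_seed <- function(master, stage) {
  stages <- c("simulate", "reconstruct", "phase", "measure", "classify")
  idx <- match(stage, stages)
  stopifnot(!is.na(idx))
  as.integer((as.numeric(master) * 48271 + 1000003 * idx) %% 2147483647)
}

# FNV-1a hash of a string, reported as 8 hex digits; used to fingerprint
# the configuration in the run manifest.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Reconstruct, unwrap and measure one pollen hologram
#'
#' The single-grain analysis chain: reconstruct the complex field (sparse or
#' Fourier), wrap and unwrap the phase, flatten the background (border-frame
#' plane fit, then refined against the segmentation), segment, and measure
#' the largest grain.
#'
#' @param hologram A [forward_hologram()] object.
#' @param reference The reference wave; `NULL` to estimate it from the
#'   hologram.
#' @param config A [pipeline_config()] supplying reconstruction and
#'   segmentation settings.
#' @param id Identifier for the measurement row.
#' @return A list with `measurement` (one-row tibble, or NULL if nothing was
#'   segmented), `phase` (the flattened [phase_map()]) and `mask`.
#' @export
analyse_hologram <- function(hologram, reference = NULL,
                             config = pipeline_config(), id = "pollen_1") {
  rc <- config$reconstruct
  if (is.null(reference)) reference <- estimate_reference(hologram)
  field <- if (rc$method == "sparse") {
    sparse_reconstruct(hologram, reference,
                       optim_config(epsilon = rc$epsilon,
                                    max_iters = rc$max_iters,
                                    rel_change_tol = rc$rel_change_tol,
                                    step_init = rc$step_init,
                                    balance_ratio = rc$balance_ratio,
                                    init_mode = rc$init_mode,
                                    filter_radius = rc$filter_radius))$field
  } else {
    fr <- rc$filter_radius
    if (is.null(fr)) fr <- 1 / 16
    fourier_reconstruct(hologram, reference, filter_radius = fr)
  }
  ph <- unwrap_tie(wrap_phase(field, meta = hologram$meta))
  ph <- remove_background(ph)
  sg <- config$segment
  masks <- segment_pollen(ph, min_area = sg$min_area,
                          threshold_mode = sg$threshold_mode,
                          threshold = sg$threshold,
                          floor_frac = sg$floor_frac)
  if (length(masks) == 0) {
    return(list(measurement = NULL, phase = ph, mask = NULL))
  }
  mask <- masks[[1]]
  ph <- remove_background(ph, mask = mask)
  list(measurement = measure_pollen(mask, ph, id = id),
       phase = ph, mask = mask)
}

#' Run the full simulate-reconstruct-measure-classify pipeline
#'
#' Simulates a pollen population (or analyses one you supply), reconstructs
#' each hologram, unwraps and flattens the phase, measures every grain, fits
#' the two-class mean-phase mixture, runs Welch's t-test between the stain
#' classes, flags the histogram overlap region, and writes all artifacts
#' (manifest CSV, measurements CSV, class statistics CSV, report JSON, config
#' echo YAML, optional TIFFs) under one run directory.
#'
#' @param config A [pipeline_config()].
#' @param population Optional [generate_population()] tibble; by default one
#'   is simulated from `config$simulate` with the stage seed derived from
#'   `config$seed`.
#' @return An object of class `holopollen_run`: list with `measurements`,
#'   `fit`, `ttest`, `report`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), population = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("holopollen_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meta <- do.call(optics_meta, config$optics)
  sim <- config$simulate
  if (is.null(population)) {
    population <- generate_population(
      n = sim$n, viable_fraction = sim$viable_fraction,
      mean_phase_centers = sim$mean_phase_centers,
      mean_phase_sd = sim$mean_phase_sd, shape = sim$shape,
      radius_range = sim$radius_range, tilt = sim$tilt,
      ref_amplitude = sim$ref_amplitude, texture_sd = sim$texture_sd,
      noise_sd = sim$noise_sd, seed = stage_seed(config$seed, "simulate"),
      meta = meta
    )
  }
  reference <- attr(population, "reference")

  rows <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    ref_i <- if (config$reconstruct$reference == "known") reference else NULL
    res <- analyse_hologram(population$hologram[[i]], reference = ref_i,
                            config = config, id = population$id[i])
    if (is.null(res$measurement)) next
    m <- res$measurement
    m$stain_label <- population$label[i]
    rows[[i]] <- m
    if (isTRUE(config$save_images)) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      write_hologram(population$hologram[[i]],
                     file.path(img_dir, paste0(population$id[i], "_holo.tif")))
      write_phase(res$phase,
                  file.path(img_dir, paste0(population$id[i], "_phase.tif")))
    }
  }
  measurements <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(measurements) < 4) {
    stop("Pipeline produced fewer than 4 measurable grains; cannot ",
         "classify.", call. = FALSE)
  }

  gmm_seed <- config$classify$gmm_seed
  if (is.null(gmm_seed)) gmm_seed <- stage_seed(config$seed, "classify")
  fit <- fit_two_classes(measurements, seed = gmm_seed)
  measurements <- flag_overlap(measurements, fit,
                               band_halfwidth = config$classify$band_halfwidth)
  tt <- ttest_classes(
    measurements$mean_phase[measurements$stain_label == "viable"],
    measurements$mean_phase[measurements$stain_label == "nonviable"]
  )
  accuracy <- mean(measurements$phase_label == measurements$stain_label)

  cfg_yaml <- yaml::as.yaml(unclass(config))
  report <- list(
    n_grains = nrow(measurements),
    threshold = fit$threshold,
    class_stats = as.data.frame(fit$stats),
    mixture = as.data.frame(fit$mixture),
    t_test = as.data.frame(tt),
    n_overlap = sum(measurements$overlap_flag),
    n_discordant = sum(measurements$discordant_flag),
    label_accuracy = accuracy,
    seed = config$seed,
    config_hash = fnv1a_hash(cfg_yaml)
  )

  paths <- list(
    manifest = file.path(out_dir, "manifest.csv"),
    measurements = file.path(out_dir, "measurements.csv"),
    class_stats = file.path(out_dir, "class_stats.csv"),
    report = file.path(out_dir, "report.json"),
    config = file.path(out_dir, "config.yaml")
  )
  utils::write.csv(as.data.frame(population_manifest(population)),
                   paths$manifest, row.names = FALSE)
  write_measurements(measurements, paths$measurements)
  utils::write.csv(as.data.frame(fit$stats), paths$class_stats,
                   row.names = FALSE)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(cfg_yaml, paths$config)

  structure(
    list(measurements = measurements, fit = fit, ttest = tt,
         report = report, paths = paths, out_dir = out_dir),
    class = "holopollen_run"
  )
}

#' @export
print.holopollen_run <- function(x, ...) {
  cat(sprintf(
    "<holopollen_run> %d grains, threshold = %.3f rad, accuracy vs stain = %.1f%%\n",
    x$report$n_grains, x$report$threshold, 100 * x$report$label_accuracy
  ))
  cat(sprintf("  t = %.2f (df = %.1f), p = %.3g; artifacts in %s\n",
              x$ttest$t_statistic, x$ttest$degrees_freedom,
              x$ttest$p_value, x$out_dir))
  invisible(x)
}
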