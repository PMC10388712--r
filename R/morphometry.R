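#' Segment pollen grains in a flattened phase image
#'
#' Thresholds the absolute phase to find grain cores, then grows each core
#' down to a low phase floor so that the full grain footprint — including
#' the thin rim where a phase dome tapers to zero — is captured
#' (hysteresis thresholding: Otsu or fixed seed threshold, flood floor at
#' `floor_frac` times the seed threshold). Holes are filled, components
#' smaller than `min_area` are dropped, and the remainder are labelled.
#'
#' @param phase An unwrapped, background-flattened [phase_map()].
#' @param min_area Minimum component area in pixels.
#' @param threshold_mode `"otsu"` (default) or `"fixed"`.
#' @param threshold Seed threshold in radians when `threshold_mode` is
#'   `"fixed"`.
#' @param floor_frac Flood floor as a fraction of the seed threshold;
#'   the default 0.12 captures the tapering rim of a phase dome without
#'   leaking into background noise.
#' @return A list of logical mask matrices, one per grain, ordered by
#'   decreasing area, with the seed threshold attached as attribute
#'   `"threshold"`. An empty segmentation returns an empty list (with a
#'   message), not an error.
#' @export
segment_pollen <- function(phase, min_area = 64,
                           threshold_mode = c("otsu", "fixed"),
                           threshold = NULL, floor_frac = 0.12) {
  stopifnot(inherits(phase, "phase_map"))
  if (phase$state != "unwrapped") {
    stop("Segmentation expects an unwrapped phase map.", call. = FALSE)
  }
  threshold_mode <- match.arg(threshold_mode)
  a <- abs(phase$values)
  if (max(a) == 0) {
    message("Empty segmentation: phase image is identically zero.")
    return(structure(list(), threshold = 0))
  }
  thr <- if (threshold_mode == "otsu") {
    EBImage::otsu(a, range = c(0, max(a)), levels = 256L)
  } else {
    if (is.null(threshold)) {
      stop("`threshold` must be given with threshold_mode = \"fixed\".",
           call. = FALSE)
    }
    threshold
  }
  core <- a > thr
  low <- a > floor_frac * thr
  lab <- EBImage::bwlabel(low)
  keep <- sort(unique(lab[core & lab > 0]))
  if (length(keep) == 0) {
    message("Empty segmentation: no component above the seed threshold.")
    return(structure(list(), threshold = thr))
  }
  grains <- lab * 0
  grains[lab %in% keep] <- lab[lab %in% keep]
  grains <- EBImage::fillHull(grains)
  ids <- sort(unique(grains[grains > 0]))
  masks <- lapply(ids, function(i) grains == i)
  areas <- vapply(masks, sum, numeric(1))
  masks <- masks[areas >= min_area]
  areas <- areas[areas >= min_area]
  if (length(masks) == 0) {
    message("Empty segmentation: all components below `min_area`.")
    return(structure(list(), threshold = thr))
  }
  structure(masks[order(-areas)], threshold = thr)
}

# Marching-squares contour length of a binary mask at the 0.5 level.
# Crossings sit at pixel-edge midpoints, so each 2x2 cell contributes 0,
# sqrt(2)/2, 1 or sqrt(2) grid units of boundary.
marching_squares_perimeter <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  p <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  n <- nrow(p); m <- ncol(p)
  a <- p[1:(n - 1), 1:(m - 1)]
  b <- p[1:(n - 1), 2:m]
  cc <- p[2:n, 2:m]
  d <- p[2:n, 1:(m - 1)]
  idx <- 8L * a + 4L * b + 2L * cc + d
  s <- sqrt(2) / 2
  lut <- c(0, s, s, 1, s, sqrt(2), 1, s, s, 1, sqrt(2), s, 1, s, s, 0)
  sum(lut[idx + 1L])
}

#' Quantitative parameters of one segmented pollen grain
#'
#' Computes the per-grain record used for viability analysis: area (pixels
#' and square micrometres), perimeter (marching-squares contour length),
#' mean phase (integrated phase inside the mask divided by the pixel
#' count, radians) and optical volume (integrated phase times pixel area,
#' radian square-micrometres). The object-plane pixel size is
#' `pixel_pitch / magnification`.
#'
#' @param mask Logical matrix marking the grain footprint.
#' @param phase An unwrapped [phase_map()] of the same shape.
#' @param meta [optics_meta()] for unit conversion; defaults to the one
#'   carried by `phase`.
#' @param id Identifier stored in the output row.
#' @return A one-row tibble with columns `id`, `area_px2`, `area_um2`,
#'   `perimeter_px`, `perimeter_um`, `mean_phase`, `optical_volume`.
#' @export
measure_pollen <- function(mask, phase, meta = NULL, id = "pollen_1") {
  stopifnot(inherits(phase, "phase_map"))
  if (phase$state != "unwrapped") {
    stop("Measurement expects an unwrapped phase map.", call. = FALSE)
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(phase$values)))
  if (!any(mask)) stop("Empty mask.", call. = FALSE)
  if (is.null(meta)) meta <- phase$meta
  px <- pixel_size_um(meta)
  area_px <- sum(mask)
  total_phase <- sum(phase$values[mask])
  tibble::tibble(
    id = id,
    area_px2 = area_px,
    area_um2 = area_px * px^2,
    perimeter_px = marching_squares_perimeter(mask),
    perimeter_um = marching_squares_perimeter(mask) * px,
    mean_phase = total_phase / area_px,
    optical_volume = total_phase * px^2
  )
}

#' Segment and measure every grain in a phase image
#'
#' Convenience wrapper: [segment_pollen()] then [measure_pollen()] per mask.
#'
#' @inheritParams segment_pollen
#' @param meta [optics_meta()]; defaults to the map's metadata.
#' @param id_prefix Prefix for the generated grain identifiers.
#' @return A tibble with one row per segmented grain.
#' @export
measure_phase_image <- function(phase, min_area = 64,
                                threshold_mode = c("otsu", "fixed"),
                                threshold = NULL, floor_frac = 0.12,
                                meta = NULL, id_prefix = "pollen") {
  masks <- segment_pollen(phase, min_area = min_area,
                          threshold_mode = threshold_mode,
                          threshold = threshold, floor_frac = floor_frac)
  if (length(masks) == 0) {
    return(tibble::tibble(
      id = character(), area_px2 = numeric(), area_um2 = numeric(),
      perimeter_px = numeric(), perimeter_um = numeric(),
      mean_phase = numeric(), optical_volume = numeric()
    ))
  }
  purrr::list_rbind(purrr::imap(masks, function(m, i) {
    measure_pollen(m, phase, meta = meta,
                   id = sprintf("%s_%02d", id_prefix, i))
  }))
}
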