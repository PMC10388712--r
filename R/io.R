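# Image I/O: single-channel TIFF plus a JSON sidecar recording the affine
# value mapping (stored_unit in [0,1]; physical = offset + stored * scale)
# and acquisition metadata. Holograms are stored as 16-bit integers, phase
# maps as 32-bit floats.

sidecar_path <- function(path) paste0(path, ".json")

write_image_sidecar <- function(path, fields) {
  jsonlite::write_json(fields, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_image_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("Missing metadata sidecar: expected file `", sp, "`.", call. = FALSE)
  }
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

meta_to_list <- function(meta) unclass(meta)

meta_from_list <- function(x) {
  do.call(optics_meta, x[c("wavelength", "pixel_pitch", "magnification",
                           "numerical_aperture")])
}

#' Write / read a hologram as 16-bit TIFF with JSON sidecar
#'
#' Intensities are affinely mapped to the 16-bit range; the mapping
#' (`offset`, `scale`, with `value = offset + stored_unit * scale`) and the
#' acquisition metadata are stored in `<path>.json`. Reading without the
#' sidecar is an error naming the expected file.
#'
#' @param hologram A [forward_hologram()] object.
#' @param path Output TIFF path.
#' @return `write_hologram()` returns `path` invisibly; `read_hologram()`
#'   returns a `hologram` object.
#' @export
write_hologram <- function(hologram, path) {
  stopifnot(inherits(hologram, "hologram"))
  v <- hologram$values
  offset <- min(v)
  scale <- max(v) - offset
  unit <- if (scale > 0) (v - offset) / scale else v * 0
  tiff::writeTIFF(unit, path, bits.per.sample = 16L)
  write_image_sidecar(path, list(
    kind = "hologram", offset = offset, scale = scale,
    bits = 16L, shape = dim(v), noise_sd = hologram$noise_sd,
    meta = meta_to_list(hologram$meta)
  ))
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  sc <- read_image_sidecar(path)
  unit <- tiff::readTIFF(path)
  v <- sc$offset + unit * sc$scale
  structure(list(values = v, meta = meta_from_list(sc$meta),
                 noise_sd = sc$noise_sd),
            class = "hologram")
}

#' Write / read a phase map as float32 TIFF with JSON sidecar
#'
#' Phase values are normalised to [0, 1] for storage (32-bit float samples)
#' with the affine mapping and the wrapped/unwrapped state recorded in the
#' sidecar, so the round trip is stable at single precision.
#'
#' @param phase A [phase_map()].
#' @param path Output TIFF path.
#' @return `write_phase()` returns `path` invisibly; `read_phase()` returns
#'   a `phase_map`.
#' @export
write_phase <- function(phase, path) {
  stopifnot(inherits(phase, "phase_map"))
  v <- phase$values
  offset <- min(v)
  scale <- max(v) - offset
  unit <- if (scale > 0) (v - offset) / scale else v * 0
  tiff::writeTIFF(unit, path, bits.per.sample = 32L)
  write_image_sidecar(path, list(
    kind = "phase", offset = offset, scale = scale, bits = 32L,
    shape = dim(v), state = phase$state, meta = meta_to_list(phase$meta)
  ))
  invisible(path)
}

#' @rdname write_phase
#' @export
read_phase <- function(path) {
  sc <- read_image_sidecar(path)
  unit <- tiff::readTIFF(path)
  v <- sc$offset + unit * sc$scale
  if (sc$state == "wrapped") v <- pmin(pmax(v, -pi + 1e-12), pi)
  phase_map(v, state = sc$state, meta = meta_from_list(sc$meta))
}

measurement_columns <- c(
  "id", "stain_label", "area_px2", "area_um2", "perimeter_px",
  "perimeter_um", "mean_phase", "optical_volume", "phase_label",
  "overlap_flag"
)

#' Write / read the per-grain measurement table
#'
#' CSV with a fixed, documented column order: id, stain_label, area_px2,
#' area_um2, perimeter_px, perimeter_um, mean_phase, optical_volume,
#' phase_label, overlap_flag. Missing optional columns are written as NA;
#' reading checks the schema and names any missing required column.
#'
#' @param measurements A measurements tibble.
#' @param path CSV path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns a tibble.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(is.data.frame(measurements))
  df <- as.data.frame(measurements)
  for (col in measurement_columns) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df <- df[, measurement_columns]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing) > 0) {
    stop("Measurement CSV schema error: missing column(s) ",
         paste0("`", missing, "`", collapse = ", "), ".", call. = FALSE)
  }
  tibble::as_tibble(df)
}
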