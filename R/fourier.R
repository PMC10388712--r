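# Frequencies of an n-point DFT in cycles per pixel, wrapped to (-0.5, 0.5].
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k) / n
}

#' Estimate the reference wave from an off-axis hologram
#'
#' Locates the strongest non-DC peak in the hologram's Fourier magnitude (the
#' interference sideband) and converts it to a carrier frequency in
#' cycles/pixel with sub-pixel (3x3 centroid) refinement. Because the
#' hologram is real its spectrum is conjugate-symmetric, so the sideband sign
#' is ambiguous; the returned tilt is resolved to the half-plane with
#' positive row-frequency (ties broken towards positive column-frequency).
#' The reference amplitude is estimated as the square root of the median of
#' a fringe-free (DC low-passed) intensity background, which assumes the
#' object wave is weak over most of the field.
#'
#' @param hologram A [forward_hologram()] object or intensity matrix.
#' @param dc_exclude Radius (cycles/pixel) around DC excluded from the peak
#'   search.
#' @return A [make_reference()] wave matching the hologram shape.
#' @export
estimate_reference <- function(hologram, dc_exclude = 0.03) {
  H <- hologram_values(hologram)
  n <- dim(H)
  Fh <- stats::fft(H - mean(H))
  mag <- Mod(Fh)
  fr <- fft_freqs(n[1])
  fc <- fft_freqs(n[2])
  dist2 <- outer(fr^2, fc^2, `+`)
  search <- dist2 > dc_exclude^2
  if (!any(search)) stop("Image too small to search for a carrier.", call. = FALSE)
  peak <- max(mag[search])
  floor_mag <- stats::median(mag[search])
  if (peak <= 0 || peak < 10 * floor_mag) {
    stop("No off-axis carrier: no sideband rises above the noise floor.",
         call. = FALSE)
  }
  idx <- which(mag == peak & search, arr.ind = TRUE)[1, ]

  # 3x3 centroid on squared magnitude, with periodic wraparound.
  ri <- ((idx[1] - 1) + (-1:1)) %% n[1] + 1
  ci <- ((idx[2] - 1) + (-1:1)) %% n[2] + 1
  w <- mag[ri, ci]^2
  dr <- sum((-1:1) * rowSums(w)) / sum(w)
  dc <- sum((-1:1) * colSums(w)) / sum(w)
  f_row <- wrap_unit(((idx[1] - 1) + dr) / n[1])
  f_col <- wrap_unit(((idx[2] - 1) + dc) / n[2])

  if (f_row < 0 || (f_row == 0 && f_col < 0)) {
    f_row <- -f_row
    f_col <- -f_col
  }

  # Fringe-free background: keep only the DC neighbourhood of the spectrum.
  carrier <- sqrt(f_row^2 + f_col^2)
  lp <- dist2 <= (0.4 * carrier)^2
  dc_img <- Re(stats::fft(stats::fft(H) * lp, inverse = TRUE)) / prod(n)
  amplitude <- sqrt(max(stats::median(dc_img), .Machine$double.eps))

  make_reference(n, tilt = c(f_row, f_col), amplitude = amplitude)
}

wrap_unit <- function(f) {
  f <- f - round(f)
  f
}

#' Fourier-transform (sideband demodulation) reconstruction
#'
#' The conventional single-shot reconstruction: demodulate the hologram by
#' the reference carrier, keep a circular low-pass window of `filter_radius`
#' about the shifted sideband, and divide by the reference amplitude. The
#' window is an explicit low-pass, so the recovered field is band-limited:
#' sharp edges blur. This is the baseline the TV-regularised solver is
#' measured against, and also its default initialiser.
#'
#' @param hologram A [forward_hologram()] object or intensity matrix.
#' @param reference A [make_reference()] wave consistent with the carrier.
#' @param filter_radius Low-pass radius in cycles/pixel.
#' @return A [complex_field()] with role `"reconstruction"`.
#' @export
fourier_reconstruct <- function(hologram, reference, filter_radius = 1 / 16) {
  H <- hologram_values(hologram)
  stopifnot(inherits(reference, "reference_wave"))
  if (!all(dim(H) == reference$shape)) {
    stop("Hologram and reference shapes disagree.", call. = FALSE)
  }
  carrier <- sqrt(sum(reference$tilt^2))
  if (carrier <= filter_radius) {
    stop("Sideband and DC overlap at this filter radius; reduce ",
         "`filter_radius` or increase the reference tilt.", call. = FALSE)
  }
  n <- dim(H)
  rr <- matrix(0:(n[1] - 1), n[1], n[2])
  cc <- matrix(0:(n[2] - 1), n[1], n[2], byrow = TRUE)
  # Demodulation moves the O R* term (carried at -tilt) to baseband.
  demod <- H * exp(2i * pi * (reference$tilt[1] * rr + reference$tilt[2] * cc))
  mask <- outer(fft_freqs(n[1])^2, fft_freqs(n[2])^2, `+`) <= filter_radius^2
  O <- stats::fft(stats::fft(demod) * mask, inverse = TRUE) / prod(n)
  complex_field(O / reference$amplitude, role = "reconstruction")
}
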