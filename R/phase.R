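#' Phase map container
#'
#' @param values Matrix of phase values in radians.
#' @param state `"wrapped"` (values restricted to (-pi, pi]) or
#'   `"unwrapped"`.
#' @param meta [optics_meta()] carried along for unit conversions.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(values, state = c("wrapped", "unwrapped"),
                      meta = optics_meta()) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) stop("Phase values must be finite.", call. = FALSE)
  if (state == "wrapped" && (any(values > pi) || any(values <= -pi))) {
    stop("Wrapped phase must lie in (-pi, pi].", call. = FALSE)
  }
  structure(list(values = values, state = state, meta = meta),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %s, %d x %d, range [%.3g, %.3g] rad\n",
              x$state, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Wrap any angle into (-pi, pi].
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Wrapped phase of a complex field
#'
#' The four-quadrant arctangent of the imaginary over real part, in
#' (-pi, pi]. Pixels where the field is exactly zero have no defined phase;
#' they are set to 0 and reported with a warning (downstream measurement
#' masks should exclude them).
#'
#' @param field A [complex_field()] or complex matrix.
#' @param meta [optics_meta()] to attach.
#' @return A wrapped [phase_map()].
#' @export
wrap_phase <- function(field, meta = optics_meta()) {
  v <- field_matrix(field)
  zero <- Mod(v) == 0
  phi <- atan2(Im(v), Re(v))
  phi[phi == -pi] <- pi
  if (any(zero)) {
    phi[zero] <- 0
    warning(sum(zero), " zero-amplitude pixel(s) mapped to phase 0.",
            call. = FALSE)
  }
  phase_map(phi, state = "wrapped", meta = meta)
}

# --- Unnormalised DCT-II and its inverse via length-2n FFTs -----------------
# y_k = 2 * sum_j x_j cos(pi * k * (j + 1/2) / n). Used only through the
# Poisson solver below; verified against the O(n^2) definition in tests.

dct2_cols <- function(x) {
  n <- nrow(x)
  X <- rbind(x, x[n:1, , drop = FALSE])
  Fx <- stats::mvfft(X)
  ph <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  Re(Fx[1:n, , drop = FALSE] * ph)
}

idct2_cols <- function(y) {
  n <- nrow(y)
  ph <- exp(1i * pi * (0:(n - 1)) / (2 * n))
  Fk <- y * ph
  Fm <- matrix(0i, 2 * n, ncol(y))
  Fm[1:n, ] <- Fk
  if (n > 1) {
    Fm[(n + 2):(2 * n), ] <- Conj(Fk[n:2, , drop = FALSE])
  }
  X <- Re(stats::mvfft(Fm, inverse = TRUE)) / (2 * n)
  X[1:n, , drop = FALSE]
}

dct2d <- function(x) t(dct2_cols(t(dct2_cols(x))))
idct2d <- function(y) t(idct2_cols(t(idct2_cols(y))))

#' Transport-of-intensity (Poisson) phase unwrapping
#'
#' Estimates the unwrapped phase from its wrapped version by a global,
#' residue-free least-squares route: the wrapped forward differences are a
#' consistent estimate of the true phase gradient wherever the sampling
#' satisfies Nyquist; their divergence gives a Poisson equation for the
#' continuous phase, solved with a discrete cosine transform (Neumann
#' boundary, matching a free-edge field of view). The least-squares solution
#' is then made congruent to the input by snapping it, pixel by pixel, to
#' the nearest value that differs from the wrapped input by a multiple of
#' 2*pi. The result is unique up to a global additive 2*pi*k.
#'
#' Iteratively reconstructed fields can carry tight dipole pairs of phase
#' residues (amplitude near-nulls at steep object edges); these bias any
#' residue-free solver. The gradient field is therefore estimated from a
#' lightly low-pass-filtered complex exponential of the input
#' (`smooth_sigma` pixels), which annihilates close residue dipoles; the
#' congruence step still snaps to the original, unsmoothed wrapped values,
#' so residue-free inputs are returned exactly (up to 2*pi*k).
#'
#' @param wrapped A wrapped [phase_map()].
#' @param smooth_sigma Gaussian width (pixels) of the complex-domain
#'   pre-filter for the gradient estimate; 0 disables it.
#' @return An unwrapped [phase_map()].
#' @export
unwrap_tie <- function(wrapped, smooth_sigma = 1) {
  stopifnot(inherits(wrapped, "phase_map"))
  if (wrapped$state != "wrapped") {
    stop("Input is already unwrapped.", call. = FALSE)
  }
  psi <- wrapped$values
  n <- dim(psi)
  psi_g <- if (smooth_sigma > 0) {
    Arg(gaussian_blur_fft(exp(1i * psi), smooth_sigma))
  } else {
    psi
  }
  dr <- wrap_to_pi(diff_row(psi_g))
  dc <- wrap_to_pi(diff_col(psi_g))
  dr[n[1], ] <- 0
  dc[, n[2]] <- 0
  rho <- -(diff_row_adj(dr) + diff_col_adj(dc))

  P <- dct2d(rho)
  lam <- outer(2 * cos(pi * (0:(n[1] - 1)) / n[1]),
               2 * cos(pi * (0:(n[2] - 1)) / n[2]), `+`) - 4
  lam[1, 1] <- 1
  P <- P / lam
  P[1, 1] <- 0
  phi_ls <- idct2d(P)

  # Two-stage congruence: snap first to the smoothed phase (whose branch
  # structure the least-squares surface follows), then to the original input.
  u <- phi_ls - wrap_to_pi(phi_ls - psi_g)
  phi <- u - wrap_to_pi(u - psi)
  phase_map(phi, state = "unwrapped", meta = wrapped$meta)
}

#' Remove a residual background plane from an unwrapped phase map
#'
#' Fits a least-squares plane (tilt plus offset) to the background region —
#' the exterior of `mask` if one is given, otherwise a border frame — and
#' subtracts it, then zeroes the background median. This flattens residual
#' reference-tilt mismatch and removes the global 2*pi*k unwrapping offset
#' so that the empty field of view sits at phase 0 before measurement.
#'
#' @param phase An unwrapped [phase_map()].
#' @param mask Optional logical matrix marking foreground (pollen) pixels;
#'   the plane is fitted to `!mask`.
#' @param frame Border frame width in pixels used when `mask` is `NULL`.
#' @return The flattened, unwrapped [phase_map()].
#' @export
remove_background <- function(phase, mask = NULL, frame = NULL) {
  stopifnot(inherits(phase, "phase_map"))
  if (phase$state != "unwrapped") {
    stop("`phase` must be unwrapped before background removal.", call. = FALSE)
  }
  v <- phase$values
  n <- dim(v)
  if (is.null(mask)) {
    if (is.null(frame)) frame <- max(4L, ceiling(0.05 * min(n)))
    bg <- matrix(FALSE, n[1], n[2])
    bg[c(seq_len(frame), n[1] - seq_len(frame) + 1L), ] <- TRUE
    bg[, c(seq_len(frame), n[2] - seq_len(frame) + 1L)] <- TRUE
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == n))
    bg <- !mask
  }
  if (sum(bg) < 100) {
    stop("Insufficient background: fewer than 100 pixels to fit the plane.",
         call. = FALSE)
  }
  rr <- matrix(0:(n[1] - 1), n[1], n[2])
  cc <- matrix(0:(n[2] - 1), n[1], n[2], byrow = TRUE)
  fit <- stats::lm.fit(cbind(1, rr[bg], cc[bg]), v[bg])
  plane <- fit$coefficients[1] + fit$coefficients[2] * rr +
    fit$coefficients[3] * cc
  out <- v - plane
  out <- out - stats::median(out[bg])
  phase_map(out, state = "unwrapped", meta = phase$meta)
}
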