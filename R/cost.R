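# Forward differences with replicate boundary (last difference is zero),
# and their exact discrete adjoints. The TV gradient uses the adjoints, so
# the analytic gradients match finite differences of the cost to rounding.

diff_row <- function(x) {
  n <- nrow(x)
  rbind(x[-1, , drop = FALSE] - x[-n, , drop = FALSE],
        matrix(0, 1, ncol(x)))
}

diff_col <- function(x) {
  m <- ncol(x)
  cbind(x[, -1, drop = FALSE] - x[, -m, drop = FALSE],
        matrix(0, nrow(x), 1))
}

diff_row_adj <- function(y) {
  n <- nrow(y)
  out <- rbind(matrix(0, 1, ncol(y)), y[-n, , drop = FALSE]) - y
  out[n, ] <- y[n - 1, ]
  out
}

diff_col_adj <- function(y) {
  m <- ncol(y)
  out <- cbind(matrix(0, nrow(y), 1), y[, -m, drop = FALSE]) - y
  out[, m] <- y[, m - 1]
  out
}

field_matrix <- function(object) {
  if (inherits(object, "complex_field")) return(object$values)
  if (is.matrix(object)) return(object)
  stop("`object` must be a complex_field or matrix.", call. = FALSE)
}

#' Data-fidelity and total-variation terms of the reconstruction cost
#'
#' The sparse reconstruction minimises the squared fit error between the
#' measured hologram and the interference model, plus a total-variation
#' penalty on the complex object field. The TV term is the sum over pixels
#' of `sqrt(|d/drow O|^2 + |d/dcol O|^2 + epsilon^2)` using forward
#' differences with replicate boundary; `epsilon` is the small smoothing
#' constant that also guards the TV gradient against division by zero.
#' No fixed regularisation weight multiplies the two terms: the solver
#' balances them adaptively, so `total_proxy` is their plain sum, reported
#' for monitoring only.
#'
#' @param object Current object-field estimate (`complex_field` or matrix).
#' @param reference The [make_reference()] wave.
#' @param hologram The measured [forward_hologram()] or matrix.
#' @param epsilon TV smoothing constant (> 0, or 0 for the exact TV value).
#' @return A list of class `cost_breakdown` with `data_term`, `tv_term`,
#'   `total_proxy`.
#' @export
cost_terms <- function(object, reference, hologram, epsilon = 1e-9) {
  O <- field_matrix(object)
  Rv <- reference_values(reference)
  H <- hologram_values(hologram)
  if (!all(dim(O) == dim(H)) || !all(dim(Rv) == dim(H))) {
    stop("Object, reference and hologram shapes disagree.", call. = FALSE)
  }
  W <- O + Rv
  res <- H - Mod(W)^2
  gr <- diff_row(O)
  gc <- diff_col(O)
  tv <- sum(sqrt(Mod(gr)^2 + Mod(gc)^2 + epsilon^2))
  structure(
    list(data_term = sum(res^2), tv_term = tv,
         total_proxy = sum(res^2) + tv),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> data = %.6g, tv = %.6g\n",
              x$data_term, x$tv_term))
  invisible(x)
}

#' Wirtinger gradients of the data and TV terms
#'
#' Steepest-descent directions for the complex-valued object field, taken as
#' derivatives with respect to the conjugate field. The data-term gradient is
#' `-2 * (H - |O+R|^2) * (O+R)`; the TV gradient is (half) the negative
#' divergence of the epsilon-normalised gradient field of `O`, i.e. the
#' adjoint differences applied to `grad(O) / sqrt(|grad O|^2 + epsilon^2)`.
#'
#' @inheritParams cost_terms
#' @param epsilon TV smoothing constant, must be > 0 here.
#' @return List with elements `data` and `tv`, both [complex_field()]s.
#' @export
gradients <- function(object, reference, hologram, epsilon = 1e-9) {
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be > 0.", call. = FALSE)
  }
  O <- field_matrix(object)
  Rv <- reference_values(reference)
  H <- hologram_values(hologram)
  if (!all(dim(O) == dim(H)) || !all(dim(Rv) == dim(H))) {
    stop("Object, reference and hologram shapes disagree.", call. = FALSE)
  }
  W <- O + Rv
  res <- H - Mod(W)^2
  g_data <- -2 * res * W

  gr <- diff_row(O)
  gc <- diff_col(O)
  s <- sqrt(Mod(gr)^2 + Mod(gc)^2 + epsilon^2)
  g_tv <- 0.5 * (diff_row_adj(gr / s) + diff_col_adj(gc / s))

  list(data = complex_field(g_data, role = "reconstruction"),
       tv = complex_field(g_tv, role = "reconstruction"))
}
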