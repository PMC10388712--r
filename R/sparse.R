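#' Solver settings for the TV-regularised sparse reconstruction
#'
#' @param epsilon TV smoothing constant, relative to the RMS magnitude of the
#'   initial field (> 0).
#' @param max_iters Maximum number of alternating iterations (>= 1).
#' @param rel_change_tol Stop when the relative solution change
#'   `||dO|| / ||O||` between successive iterations falls below this.
#' @param step_init Initial trial step for the backtracking data descent.
#' @param balance_ratio Length of each TV step as a fraction of the preceding
#'   data-step displacement, in (0, 1]. This replaces a fixed regularisation
#'   weight: the two descent moves are balanced against each other instead.
#' @param init_mode Initialisation: `"fourier"` (the sideband-demodulation
#'   baseline) or `"zeros"`.
#' @param filter_radius Low-pass radius (cycles/pixel) used for the Fourier
#'   initialiser. `NULL` (default) picks the widest alias-free window,
#'   0.48 times the carrier frequency, so the initial field keeps as much
#'   bandwidth as the carrier separation allows.
#' @return A list of class `optim_config`.
#' @export
optim_config <- function(epsilon = 1e-9,
                         max_iters = 300,
                         rel_change_tol = 1e-4,
                         step_init = 0.05,
                         balance_ratio = 0.5,
                         init_mode = c("fourier", "zeros"),
                         filter_radius = NULL) {
  init_mode <- match.arg(init_mode)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be > 0.", call. = FALSE)
  }
  if (!is.numeric(max_iters) || max_iters < 1) {
    stop("`max_iters` must be >= 1.", call. = FALSE)
  }
  if (!is.numeric(rel_change_tol) || rel_change_tol <= 0) {
    stop("`rel_change_tol` must be > 0.", call. = FALSE)
  }
  if (!is.numeric(balance_ratio) || balance_ratio <= 0 || balance_ratio > 1) {
    stop("`balance_ratio` must lie in (0, 1].", call. = FALSE)
  }
  structure(
    list(epsilon = epsilon, max_iters = as.integer(max_iters),
         rel_change_tol = rel_change_tol, step_init = step_init,
         balance_ratio = balance_ratio, init_mode = init_mode,
         filter_radius = filter_radius),
    class = "optim_config"
  )
}

frob <- function(x) sqrt(sum(Mod(x)^2))

#' TV-regularised sparse reconstruction of the object field
#'
#' Recovers the complex object wave from a single off-axis hologram by
#' adaptive alternating minimisation of the data-fit and total-variation
#' terms. Each iteration takes (a) a backtracking steepest-descent step on
#' the data term (the step is accepted only if it lowers the data misfit) and
#' (b) a TV-descent step whose length is scaled so the solution change it
#' induces is `balance_ratio` times the data-step displacement, with an
#' additional safeguard that halves the TV step while it would undo more of
#' the data-term reduction than the data step just achieved. Because the TV
#' step length is slaved to the data step, no regularisation constant has to
#' be tuned, and both moves shrink together as the iteration converges. The
#' loop stops when the relative solution change drops below
#' `rel_change_tol`, or at `max_iters`.
#'
#' @param hologram The measured [forward_hologram()] or intensity matrix.
#' @param reference The [make_reference()] wave (known from the
#'   interferometer geometry, or from [estimate_reference()]).
#' @param config An [optim_config()].
#' @param init Optional initial field (`complex_field` or matrix); overrides
#'   `config$init_mode`.
#' @return An object of class `sparse_recon`: list with `field` (the
#'   reconstructed [complex_field()]), `trace` (tibble with per-iteration
#'   `iteration`, `data_pre`, `data_term`, `tv_term`, `total_proxy`,
#'   `step`, `rel_change`), `iterations`, `converged`.
#' @seealso [fourier_reconstruct()] for the band-limited baseline.
#' @export
sparse_reconstruct <- function(hologram, reference, config = optim_config(),
                               init = NULL) {
  stopifnot(inherits(config, "optim_config"))
  H <- hologram_values(hologram)
  Rv <- reference_values(reference)
  if (!all(dim(H) == dim(Rv))) {
    stop("Hologram and reference shapes disagree.", call. = FALSE)
  }

  O <- if (!is.null(init)) {
    field_matrix(init)
  } else if (config$init_mode == "fourier") {
    fr <- config$filter_radius
    if (is.null(fr)) {
      if (!inherits(reference, "reference_wave")) {
        stop("Adaptive `filter_radius` needs a reference_wave; give an ",
             "explicit radius otherwise.", call. = FALSE)
      }
      fr <- 0.48 * sqrt(sum(reference$tilt^2))
    }
    fourier_reconstruct(hologram, reference, filter_radius = fr)$values
  } else {
    matrix(0 + 0i, nrow(H), ncol(H))
  }

  rms <- frob(O) / sqrt(length(O))
  eps_abs <- config$epsilon * max(rms, 1)

  data_of <- function(X) {
    res <- H - Mod(X + Rv)^2
    sum(res^2)
  }
  tv_of <- function(X) {
    sum(sqrt(Mod(diff_row(X))^2 + Mod(diff_col(X))^2 + eps_abs^2))
  }

  D0 <- data_of(O)
  D_best <- D0
  t_step <- config$step_init
  trace <- vector("list", config$max_iters)
  converged <- FALSE
  iterations <- 0L

  for (k in seq_len(config$max_iters)) {
    D_pre <- D0
    g <- gradients(O, Rv, H, epsilon = eps_abs)

    # (a) backtracking steepest descent on the data term
    gd <- g$data$values
    gd_norm <- frob(gd)
    O1 <- O
    D1 <- D0
    if (gd_norm > 0) {
      # Aim below the best data value seen so far (keeps the recorded data
      # term non-increasing even though the TV step may raise it a little);
      # fall back to a plain decrease from the current point.
      t_try <- t_step * 2
      accepted <- FALSE
      fallback <- NULL
      for (bt in 1:60) {
        cand <- O - t_try * gd
        Dc <- data_of(cand)
        if (Dc < min(D0, D_best)) {
          O1 <- cand
          D1 <- Dc
          t_step <- t_try
          accepted <- TRUE
          break
        }
        if (is.null(fallback) && Dc < D0) fallback <- list(O = cand, D = Dc, t = t_try)
        t_try <- t_try / 2
      }
      if (!accepted && !is.null(fallback)) {
        O1 <- fallback$O
        D1 <- fallback$D
        t_step <- fallback$t
        accepted <- TRUE
      }
      if (!accepted && D0 > 0 && gd_norm * t_try > 1e3 * .Machine$double.eps * frob(O)) {
        # Data term cannot be decreased along the steepest-descent ray.
        stop("Optimisation failure: data term not reducible after ",
             "backtracking exhaustion.", call. = FALSE)
      }
    }
    delta_data <- frob(O1 - O)
    D_best <- min(D_best, D1)

    # (b) TV step, length balanced against the data-step displacement
    gt <- gradients(O1, Rv, H, epsilon = eps_abs)$tv$values
    gt_norm <- frob(gt)
    O2 <- O1
    if (gt_norm > 0 && delta_data > 0) {
      s <- config$balance_ratio * delta_data / gt_norm
      drop_k <- D0 - D1
      for (bt in 1:30) {
        cand <- O1 - s * gt
        if (data_of(cand) <= D1 + 0.9 * drop_k) break
        s <- s / 2
      }
      O2 <- O1 - s * gt
    }

    rel <- frob(O2 - O) / max(frob(O), .Machine$double.eps)
    D0 <- data_of(O2)
    tv_now <- tv_of(O2)
    trace[[k]] <- c(iteration = k, data_pre = D_pre, data_term = D1,
                    tv_term = tv_now, total_proxy = D1 + tv_now,
                    step = t_step, rel_change = rel)
    O <- O2
    iterations <- k
    if (rel < config$rel_change_tol) {
      converged <- TRUE
      break
    }
  }

  trace_df <- tibble::as_tibble(do.call(rbind, trace[seq_len(iterations)]))
  structure(
    list(field = complex_field(O, role = "reconstruction"),
         trace = trace_df, iterations = iterations, converged = converged,
         epsilon_abs = eps_abs, config = config),
    class = "sparse_recon"
  )
}

#' @export
print.sparse_recon <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<sparse_recon> %d iterations (%s), data = %.4g, tv = %.4g\n",
    x$iterations, if (x$converged) "converged" else "max_iters",
    last$data_term, last$tv_term
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn sparse_reconstruct Per-iteration cost trace as a tibble.
#' @param x A `sparse_recon` object.
#' @param ... Unused.
#' @method tidy sparse_recon
#' @export
tidy.sparse_recon <- function(x, ...) x$trace

#' @describeIn sparse_reconstruct One-row summary of the optimisation run.
#' @method glance sparse_recon
#' @export
glance.sparse_recon <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    data_term = last$data_term,
    tv_term = last$tv_term,
    rel_change = last$rel_change
  )
}
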