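#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster plot of a phase map
#'
#' @param phase A [phase_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_map
#' @export
autoplot.phase_map <- function(phase, ...) {
  v <- phase$values
  df <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    phase = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s phase map", phase$state)) +
    ggplot2::theme_minimal()
}

#' Cost trace of a sparse reconstruction run
#'
#' @param object A [sparse_reconstruct()] result.
#' @param ... Unused.
#' @return A ggplot object with the data and TV terms per iteration.
#' @method autoplot sparse_recon
#' @export
autoplot.sparse_recon <- function(object, ...) {
  tr <- object$trace
  df <- tibble::tibble(
    iteration = rep(tr$iteration, 2),
    term = rep(c("data", "TV"), each = nrow(tr)),
    value = c(tr$data_term, tr$tv_term)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "cost term",
                  title = "Alternating minimisation trace") +
    ggplot2::theme_minimal()
}

#' Mean-phase histogram with fitted mixture and threshold
#'
#' The report figure: Freedman-Diaconis-binned histogram of per-grain mean
#' phase, the two fitted Gaussian components, and the class threshold.
#' Binning is presentation only; the classifier uses the raw values.
#'
#' @param object A [fit_two_classes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot viability_fit
#' @export
autoplot.viability_fit <- function(object, ...) {
  x <- object$data$mean_phase
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(x)) / 10
  grid <- seq(min(x) - 1, max(x) + 1, length.out = 400)
  mix <- object$mixture
  dens <- purrr::list_rbind(purrr::map(seq_len(nrow(mix)), function(k) {
    tibble::tibble(
      mean_phase = grid,
      count = length(x) * bw * mix$weight[k] *
        stats::dnorm(grid, mix$mu[k], mix$sigma[k]),
      component = mix$component[k]
    )
  }))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean_phase)) +
    ggplot2::geom_histogram(ggplot2::aes(fill = .data$phase_label),
                            binwidth = bw, alpha = 0.6, colour = "grey30") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$count,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "mean phase (rad)", y = "grains",
                  fill = "phase call", colour = "component",
                  title = "Mean-phase histogram and two-class mixture") +
    ggplot2::theme_minimal()
}
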