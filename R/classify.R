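#' Two-class Gaussian mixture on per-grain mean phase
#'
#' Operationalises the "two distinct peaks" structure of the mean-phase
#' histogram: fits a two-component univariate Gaussian mixture by EM
#' (k-means initialisation under a fixed seed, unequal variances) and places
#' the class threshold at the equal-posterior point between the component
#' means. The higher-mean component is labelled `viable`. Per-class counts,
#' means and standard deviations are computed from the resulting partition
#' (threshold cut).
#'
#' @param measurements A data frame with a `mean_phase` column (radians), or
#'   a numeric vector of mean phases. At least 4 values are required.
#' @param seed Seed for the k-means initialisation.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `viability_fit`: list with `threshold`
#'   (radians), `stats` (tibble: class, n, mean, sd), `mixture` (tibble:
#'   component, weight, mu, sigma), `data` (input values with `phase_label`),
#'   `loglik`, `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 8.72, 0.8), rnorm(50, 4.26, 0.8))
#' fit <- fit_two_classes(x)
#' fit$threshold
#' @export
fit_two_classes <- function(measurements, seed = 1, max_iter = 500,
                            tol = 1e-10) {
  x <- if (is.data.frame(measurements)) {
    if (!"mean_phase" %in% names(measurements)) {
      stop("`measurements` must contain a `mean_phase` column.", call. = FALSE)
    }
    measurements$mean_phase
  } else {
    as.numeric(measurements)
  }
  if (length(x) < 4) {
    stop("Degenerate fit: need at least 4 measurements.", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Degenerate fit: all mean-phase values are identical.", call. = FALSE)
  }

  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = 2, nstart = 10)
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  z <- match(km$cluster, ord)
  sg <- vapply(1:2, function(k) {
    s <- stats::sd(x[z == k])
    if (!is.finite(s) || s == 0) 0.05 * stats::sd(x) else s
  }, numeric(1))
  w <- vapply(1:2, function(k) mean(z == k), numeric(1))

  sigma_floor <- 1e-6 * stats::sd(x)
  loglik <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    new_ll <- sum(log(tot))
    w <- c(mean(r), mean(1 - r))
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sg <- c(sqrt(sum(r * (x - mu[1])^2) / sum(r)),
            sqrt(sum((1 - r) * (x - mu[2])^2) / sum(1 - r)))
    sg <- pmax(sg, sigma_floor)
    if (is.finite(loglik) && abs(new_ll - loglik) < tol * (1 + abs(new_ll))) {
      converged <- TRUE
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  if (any(w < 0.02)) {
    stop("Degenerate fit: a mixture component collapsed (weight < 0.02).",
         call. = FALSE)
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w)
  }

  threshold <- equal_posterior_point(w, mu, sg)
  lab <- ifelse(x > threshold, "viable", "nonviable")
  stats_tbl <- tibble::tibble(
    class = c("nonviable", "viable"),
    n = c(sum(lab == "nonviable"), sum(lab == "viable")),
    mean = c(mean(x[lab == "nonviable"]), mean(x[lab == "viable"])),
    sd = c(stats::sd(x[lab == "nonviable"]), stats::sd(x[lab == "viable"]))
  )
  out <- list(
    threshold = threshold,
    stats = stats_tbl,
    mixture = tibble::tibble(
      component = c("nonviable", "viable"),
      weight = w, mu = mu, sigma = sg
    ),
    data = tibble::tibble(mean_phase = x, phase_label = lab),
    loglik = loglik, iterations = it, converged = converged
  )
  class(out) <- "viability_fit"
  out
}

# Equal-posterior crossing of two weighted normals, between their means.
equal_posterior_point <- function(w, mu, sg) {
  g <- function(x) {
    (log(w[1]) - log(sg[1]) - (x - mu[1])^2 / (2 * sg[1]^2)) -
      (log(w[2]) - log(sg[2]) - (x - mu[2])^2 / (2 * sg[2]^2))
  }
  lo <- min(mu); hi <- max(mu)
  if (g(lo) * g(hi) < 0) {
    stats::uniroot(g, c(lo, hi), tol = 1e-12 * (1 + hi - lo))$root
  } else {
    # Pathological weights: fall back to the sd-weighted midpoint.
    (sg[2] * mu[1] + sg[1] * mu[2]) / (sg[1] + sg[2])
  }
}

#' @export
print.viability_fit <- function(x, ...) {
  cat(sprintf("<viability_fit> threshold = %.3f rad, loglik = %.2f (%d EM iters)\n",
              x$threshold, x$loglik, x$iterations))
  print(x$stats)
  invisible(x)
}

#' @describeIn fit_two_classes Mixture components as a tibble.
#' @param x A `viability_fit` object.
#' @param ... Unused.
#' @method tidy viability_fit
#' @export
tidy.viability_fit <- function(x, ...) x$mixture

#' @describeIn fit_two_classes One-row model summary.
#' @method glance viability_fit
#' @export
glance.viability_fit <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    loglik = x$loglik,
    n = nrow(x$data),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Welch's two-sample t-test on per-class mean phases
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite degrees of
#' freedom, two-sided), used to confirm that the two mean-phase classes
#' have clearly different means.
#'
#' @param group_a,group_b Numeric vectors of mean phases, each of length
#'   >= 2.
#' @return A one-row tibble: `t_statistic`, `degrees_freedom`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
ttest_classes <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("Each group needs at least 2 values.", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(
    t_statistic = unname(ht$statistic),
    degrees_freedom = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(group_a),
    mean_b = mean(group_b)
  )
}

#' Flag grains in the histogram overlap region
#'
#' Marks grains whose mean phase lies within `band_halfwidth` of the class
#' threshold — the region where the viable and non-viable distributions
#' overlap and a single-feature call is unreliable. If a `stain_label`
#' column is present, grains whose stain call disagrees with the phase call
#' are flagged separately (`discordant_flag`).
#'
#' @param measurements Tibble with `mean_phase` and optionally `stain_label`.
#' @param fit A [fit_two_classes()] object, or a numeric threshold in
#'   radians.
#' @param band_halfwidth Half-width of the overlap band, radians. Defaults
#'   to half the pooled within-class standard deviation when `fit` is a
#'   `viability_fit`.
#' @return The measurements tibble with `phase_label`, `overlap_flag` and
#'   (when stain labels exist) `discordant_flag` columns added.
#' @export
flag_overlap <- function(measurements, fit, band_halfwidth = NULL) {
  stopifnot(is.data.frame(measurements), "mean_phase" %in% names(measurements))
  if (inherits(fit, "viability_fit")) {
    threshold <- fit$threshold
    if (is.null(band_halfwidth)) {
      st <- fit$stats
      pooled <- sqrt(sum((st$n - 1) * st$sd^2) / sum(st$n - 1))
      band_halfwidth <- 0.5 * pooled
    }
  } else {
    threshold <- as.numeric(fit)
    if (is.null(band_halfwidth)) {
      stop("`band_halfwidth` is required when `fit` is a bare threshold.",
           call. = FALSE)
    }
  }
  out <- dplyr::mutate(
    tibble::as_tibble(measurements),
    phase_label = ifelse(.data$mean_phase > threshold, "viable", "nonviable"),
    overlap_flag = abs(.data$mean_phase - threshold) < band_halfwidth
  )
  if ("stain_label" %in% names(out)) {
    out <- dplyr::mutate(
      out,
      discordant_flag = !is.na(.data$stain_label) &
        .data$stain_label != .data$phase_label
    )
  }
  attr(out, "threshold") <- threshold
  attr(out, "band_halfwidth") <- band_halfwidth
  out
}
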