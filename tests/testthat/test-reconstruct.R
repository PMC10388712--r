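test_that("reference estimation recovers the carrier", {
  R <- make_reference(c(256, 256), tilt = c(0, 1 / 8))
  H <- forward_hologram(matrix(0, 256, 256), R, object_amplitude = 0.5)
  est <- estimate_reference(H)
  expect_lt(max(abs(est$tilt - c(0, 1 / 8))), 0.002)

  # both-signs tilt resolved to the positive-row-frequency half-plane
  R2 <- make_reference(c(256, 256), tilt = c(1 / 8, -1 / 8))
  ph <- centered_phantom(shape = c(256, 256), radius = 40, peak = 6)
  est2 <- estimate_reference(forward_hologram(ph, R2))
  expect_lt(max(abs(est2$tilt - c(1 / 8, -1 / 8))), 0.002)

  # no off-axis carrier: degenerate input
  H0 <- forward_hologram(matrix(0, 128, 128),
                         make_reference(c(128, 128), tilt = c(0, 0)),
                         object_amplitude = 0.5)
  expect_error(estimate_reference(H0), "carrier")
})

test_that("Fourier reconstruction round-trips simple objects", {
  R <- make_reference(c(128, 128), tilt = c(0, 1 / 8))
  H <- forward_hologram(matrix(0, 128, 128), R, object_amplitude = 0.8)
  O <- fourier_reconstruct(H, R, filter_radius = 1 / 16)
  central <- Mod(O$values[33:96, 33:96])
  expect_lt(max(abs(central - 0.8)) / 0.8, 0.02)

  # smooth Gaussian phase bump is inside the filter band
  rr <- matrix(0:127, 128, 128)
  phi <- 2 * exp(-((rr - 63.5)^2 + (t(rr) - 63.5)^2) / (2 * 20^2))
  Hg <- forward_hologram(phi, R)
  Og <- fourier_reconstruct(Hg, R, filter_radius = 1 / 16)
  w <- wrap_phase(Og)$values
  centre <- as.matrix(expand.grid(33:96, 33:96))
  expect_lt(sqrt(mean((w[centre] - phi[centre])^2)), 0.05)

  # linearity: zero hologram gives the zero field
  Oz <- fourier_reconstruct(matrix(0, 128, 128), R, filter_radius = 1 / 16)
  expect_equal(max(Mod(Oz$values)), 0, tolerance = 1e-14)

  expect_error(fourier_reconstruct(H, R, filter_radius = 0.2), "overlap")
})

test_that("conjugate sideband yields the conjugate field", {
  ph <- centered_phantom(shape = c(128, 128), radius = 30, peak = 2)
  R <- make_reference(c(128, 128), tilt = c(0.15, 0.1))
  H <- forward_hologram(ph, R)
  Rc <- make_reference(c(128, 128), tilt = -c(0.15, 0.1))
  O_plus <- fourier_reconstruct(H, R, filter_radius = 1 / 16)$values
  O_minus <- fourier_reconstruct(H, Rc, filter_radius = 1 / 16)$values
  expect_lt(max(Mod(O_minus - Conj(O_plus))), 1e-8)
})

test_that("cost terms match their closed forms", {
  R <- make_reference(c(16, 16), tilt = c(0.1, -0.2))
  O <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  H_consistent <- Mod(O + R$values)^2
  ct <- cost_terms(O, R, H_consistent, epsilon = 1e-3)
  expect_equal(ct$data_term, 0, tolerance = 1e-18)

  # constant field: TV term collapses to the epsilon floor
  Oc <- matrix(1 + 2i, 16, 16)
  ct2 <- cost_terms(Oc, R, H_consistent, epsilon = 1e-9)
  expect_lt(ct2$tv_term, 16 * 16 * 1e-8)

  # half-zero / half-one step image: one unit jump per row
  N <- 12
  step <- matrix(rep(c(rep(0, N / 2), rep(1, N / 2)), each = N), N, N)
  Rs <- make_reference(c(N, N), tilt = c(0.1, 0.1))
  ct3 <- cost_terms(step, Rs, matrix(1, N, N), epsilon = 0)
  expect_equal(ct3$tv_term, N)

  expect_error(cost_terms(O, R, matrix(1, 8, 8)), "shapes")
})

test_that("Wirtinger gradients agree with finite differences of the cost", {
  set.seed(5)
  for (n in c(8, 16)) {
    O <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
    R <- make_reference(c(n, n), tilt = runif(2, -0.3, 0.3),
                        amplitude = runif(1, 0.5, 1.5))
    H <- matrix(abs(rnorm(n^2, mean = 2)), n, n)
    eps <- 0.05
    g <- gradients(O, R, H, epsilon = eps)
    h <- 1e-6
    num_d <- matrix(0i, n, n)
    num_t <- matrix(0i, n, n)
    both <- function(Om) {
      ct <- cost_terms(Om, R, H, epsilon = eps)
      c(ct$data_term, ct$tv_term)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        E <- matrix(0, n, n); E[i, j] <- 1
        fr <- (both(O + h * E) - both(O - h * E)) / (2 * h)
        fi <- (both(O + 1i * h * E) - both(O - 1i * h * E)) / (2 * h)
        num_d[i, j] <- 0.5 * (fr[1] + 1i * fi[1])
        num_t[i, j] <- 0.5 * (fr[2] + 1i * fi[2])
      }
    }
    expect_lt(max(Mod(g$data$values - num_d)) / max(Mod(num_d)), 1e-5)
    expect_lt(max(Mod(g$tv$values - num_t)) / max(Mod(num_t)), 1e-5)
  }
  expect_error(gradients(matrix(0i, 4, 4), make_reference(c(4, 4)),
                         matrix(1, 4, 4), epsilon = 0), "epsilon")
})

test_that("consistent data makes both gradients vanish where expected", {
  R <- make_reference(c(16, 16), tilt = c(0.12, 0.21))
  O <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  H <- Mod(O + R$values)^2
  g <- gradients(O, R, H, epsilon = 1e-6)
  expect_equal(max(Mod(g$data$values)), 0, tolerance = 1e-12)
  gc <- gradients(matrix(3 - 1i, 16, 16), R, H, epsilon = 1e-6)
  expect_equal(max(Mod(gc$tv$values)), 0, tolerance = 1e-9)
})

test_that("sparse reconstruction recovers a smooth dome and keeps its contracts", {
  ph <- centered_phantom(shape = c(96, 96), radius = 30, peak = 6)
  R <- make_reference(c(96, 96), tilt = c(0.25, 0.25))
  H <- forward_hologram(ph, R)
  sr <- sparse_reconstruct(H, R)
  rec <- recover_phase(sr$field, mask = ph$true_mask)
  expect_lt(masked_rmse(rec$values, ph$true_phase, erode_mask(ph$true_mask)),
            0.1)
  # backtracking contract: every accepted data step decreases the data term
  expect_true(all(sr$trace$data_term <= sr$trace$data_pre))
  expect_true(all(diff(sr$trace$data_term) <= 0))
  # TV term stays bounded along the trajectory
  expect_lt(max(sr$trace$tv_term), 10 * sr$trace$tv_term[1])
})

test_that("a consistent initial field is a fixed point", {
  ph <- centered_phantom(shape = c(64, 64), radius = 20, peak = 2)
  R <- make_reference(c(64, 64), tilt = c(0.25, 0.25))
  H <- forward_hologram(ph, R)
  O_true <- exp(1i * ph$true_phase)
  cfg <- optim_config(max_iters = 1, rel_change_tol = 1e-4)
  sr <- sparse_reconstruct(H, R, cfg, init = O_true)
  rel <- sr$trace$rel_change[1]
  expect_lt(rel, cfg$rel_change_tol)
})

test_that("sparse reconstruction beats the Fourier baseline on sharp edges", {
  cyl <- centered_phantom(shape = c(128, 128), radius = 30, peak = 2,
                          profile = "cylinder")
  R <- make_reference(c(128, 128), tilt = c(0.25, 0.25))
  H <- forward_hologram(cyl, R)
  mask <- erode_mask(cyl$true_mask)
  err_f <- masked_rmse(
    recover_phase(fourier_reconstruct(H, R, 1 / 16), cyl$true_mask)$values,
    cyl$true_phase, mask)
  err_s <- masked_rmse(
    recover_phase(sparse_reconstruct(H, R)$field, cyl$true_mask)$values,
    cyl$true_phase, mask)
  expect_lte(err_s, err_f)
})

test_that("tidy and glance expose the optimisation trace", {
  ph <- centered_phantom(shape = c(48, 48), radius = 14, peak = 2)
  R <- make_reference(c(48, 48), tilt = c(0.25, 0.25))
  sr <- sparse_reconstruct(forward_hologram(ph, R), R,
                           optim_config(max_iters = 10))
  td <- tidy(sr)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("iteration", "data_term", "tv_term") %in% names(td)))
  gl <- glance(sr)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$iterations, sr$iterations)
})
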