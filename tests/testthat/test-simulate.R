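test_that("hemispherical phantom has the analytic profile", {
  ph <- centered_phantom(shape = c(128, 128), radius = 40, peak = 9)
  ctr <- ph$true_phase[65, 65]
  expect_equal(ctr, 9, tolerance = 1e-3)
  # profile vanishes at the rim and outside the mask
  expect_equal(ph$true_phase[65, 65 + 41], 0)
  expect_true(all(ph$true_phase[!ph$true_mask] == 0))
  # closed-form mean of sqrt(1 - rho^2) over the unit disk is 2/3
  expect_equal(phantom_mean_phase(ph), 6, tolerance = 0.01 * 6)
})

test_that("non-viable phantom keeps its interior below the rim height", {
  ph <- centered_phantom(shape = c(128, 128), radius = 40, peak = 1,
                         label = "nonviable")
  rr <- matrix(0:127, 128, 128)
  rho <- sqrt((rr - 63.5)^2 + (t(rr) - 63.5)^2) / 40
  expect_lte(max(ph$true_phase[rho < 0.7]), 1)
  expect_equal(ph$rim_phase, 1)
  expect_true(all(ph$true_phase >= 0))
})

test_that("phantom validation catches bad geometry", {
  expect_error(make_phantom("viable", shape = c(64, 64), center = c(5, 32),
                            radius = 20), "bounds")
  expect_error(make_phantom("viable", shape = c(64, 64), radius = 2),
               "radius")
  expect_error(make_phantom("viable", shape = c(64, 64), radius = 10,
                            peak_phase = -1), "peak_phase")
})

test_that("reference wave is a unit-modulus tilted plane", {
  R0 <- make_reference(c(16, 16), tilt = c(0, 0), amplitude = 1)
  expect_true(all(abs(R0$values - 1) < 1e-12))
  R1 <- make_reference(c(16, 16), tilt = c(0, 1 / 8), amplitude = 1)
  # half a period along 4 columns: phase pi
  expect_equal(R1$values[1, 5], complex(real = -1, imaginary = 0),
               tolerance = 1e-12)
  R2 <- make_reference(c(16, 16), tilt = c(0.11, -0.07), amplitude = 2.5)
  expect_equal(range(Mod(R2$values)), c(2.5, 2.5), tolerance = 1e-12)
  expect_error(make_reference(c(16, 16), tilt = c(0.5, 0)), "Nyquist")
})

test_that("forward hologram realises the interference model", {
  R <- make_reference(c(32, 32), tilt = c(0, 1 / 8))
  zero_obj <- forward_hologram(matrix(0, 32, 32), R, object_amplitude = 0)
  expect_equal(max(abs(zero_obj$values - 1)), 0, tolerance = 1e-12)

  flat <- forward_hologram(matrix(0, 32, 32),
                           make_reference(c(32, 32), tilt = c(0, 0)))
  expect_equal(max(abs(flat$values - 4)), 0, tolerance = 1e-12)

  # |1 + exp(i theta)|^2 = 2 + 2 cos(theta), period 8 px along columns
  fr <- forward_hologram(matrix(0, 32, 32), R)
  cols <- 0:31
  expect_equal(fr$values[1, ], 2 + 2 * cos(2 * pi * cols / 8),
               tolerance = 1e-12)
  expect_equal(min(fr$values), 0, tolerance = 1e-12)
  expect_equal(max(fr$values), 4, tolerance = 1e-12)

  expect_error(forward_hologram(matrix(0, 16, 16), R), "shapes")
})

test_that("holograms are nonnegative and fringes bend inside the grain", {
  set.seed(42)
  for (k in 1:5) {
    phi <- matrix(runif(32 * 32, -3, 3), 32, 32)
    amp <- matrix(runif(32 * 32, 0, 2), 32, 32)
    R <- make_reference(c(32, 32), tilt = runif(2, -0.3, 0.3),
                        amplitude = runif(1, 0.5, 2))
    H <- forward_hologram(phi, R, object_amplitude = amp)
    expect_gte(min(H$values), 0)
  }

  # demodulated local fringe phase differs inside the phantom support
  ph <- centered_phantom(shape = c(128, 128), radius = 40, peak = 6)
  R <- make_reference(c(128, 128), tilt = c(0.25, 0.25))
  H <- forward_hologram(ph, R)
  dem <- recover_phase(fourier_reconstruct(H, R, filter_radius = 0.1))
  inside <- mean(abs(dem$values[erode_mask(ph$true_mask, 4)]))
  outside <- mean(abs(dem$values[!ph$true_mask]))
  expect_gt(inside, 10 * outside)
})

test_that("population generator hits its class targets reproducibly", {
  pop <- generate_population(n = 10, viable_fraction = 1, mean_phase_sd = 0,
                             shape = c(96, 96), radius_range = c(25, 32),
                             texture_sd = 0, noise_sd = 0, seed = 7)
  means <- vapply(pop$phantom, phantom_mean_phase, numeric(1))
  expect_equal(means, rep(8.72, 10), tolerance = 0.01)

  # same seed twice: bitwise-identical holograms
  pop2 <- generate_population(n = 10, viable_fraction = 1, mean_phase_sd = 0,
                              shape = c(96, 96), radius_range = c(25, 32),
                              texture_sd = 0, noise_sd = 0, seed = 7)
  expect_identical(pop$hologram[[3]]$values, pop2$hologram[[3]]$values)

  # class counts within the binomial 99% interval around n/2
  pop3 <- generate_population(n = 200, viable_fraction = 0.5,
                              shape = c(96, 96), radius_range = c(25, 32),
                              noise_sd = 0, seed = 11)
  n_viable <- sum(pop3$label == "viable")
  expect_gte(n_viable, qbinom(0.005, 200, 0.5))
  expect_lte(n_viable, qbinom(0.995, 200, 0.5))

  expect_error(generate_population(n = 0), "n")
})

test_that("non-viable grains are scaled to their target mean phase", {
  pop <- generate_population(n = 6, viable_fraction = 0, mean_phase_sd = 0,
                             shape = c(96, 96), radius_range = c(25, 32),
                             texture_sd = 0, noise_sd = 0, seed = 3)
  means <- vapply(pop$phantom, phantom_mean_phase, numeric(1))
  expect_equal(means, rep(4.26, 6), tolerance = 0.01)
})
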