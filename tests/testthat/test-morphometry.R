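test_that("segmentation recovers a single phantom footprint", {
  ph <- centered_phantom(shape = c(192, 192), radius = 40, peak = 8)
  pm <- phase_map(ph$true_phase, "unwrapped")
  masks <- segment_pollen(pm)
  expect_length(masks, 1)
  iou <- sum(masks[[1]] & ph$true_mask) / sum(masks[[1]] | ph$true_mask)
  expect_gte(iou, 0.95)
})

test_that("segmentation handles empty and multi-grain images", {
  empty <- phase_map(matrix(0, 64, 64), "unwrapped")
  expect_message(masks <- segment_pollen(empty), "Empty")
  expect_length(masks, 0)

  two <- matrix(0, 192, 192)
  a <- make_phantom("viable", shape = c(192, 192), center = c(50, 50),
                    radius = 25, peak_phase = 8)
  b <- make_phantom("viable", shape = c(192, 192), center = c(140, 130),
                    radius = 30, peak_phase = 6)
  two <- a$true_phase + b$true_phase
  masks <- segment_pollen(phase_map(two, "unwrapped"))
  expect_length(masks, 2)
  centres <- t(vapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    colMeans(idx) - 1
  }, numeric(2)))
  centres <- centres[order(centres[, 1]), ]
  expect_lt(max(abs(centres[1, ] - c(50, 50))), 2)
  expect_lt(max(abs(centres[2, ] - c(140, 130))), 2)
})

test_that("measurements follow their defining formulas", {
  meta <- optics_meta(pixel_pitch = 5.86, magnification = 40)
  px <- pixel_size_um(meta)

  # perfect disk: pixel-count area close to pi r^2
  ph <- centered_phantom(shape = c(128, 128), radius = 40, peak = 9)
  m <- measure_pollen(ph$true_mask, phase_map(ph$true_phase, "unwrapped",
                                              meta = meta))
  expect_equal(m$area_px2, pi * 40^2, tolerance = 0.02 * pi * 40^2)
  expect_equal(m$area_um2, m$area_px2 * px^2)

  # hemispherical phantom: mean phase is (2/3) peak
  expect_equal(m$mean_phase, 6, tolerance = 0.01 * 6)

  # constant phase: mean exact, optical volume = c * area
  cst <- matrix(0, 128, 128); cst[ph$true_mask] <- 1.7
  mc <- measure_pollen(ph$true_mask, phase_map(cst, "unwrapped", meta = meta))
  expect_equal(mc$mean_phase, 1.7)
  expect_equal(mc$optical_volume, 1.7 * mc$area_um2)

  # internal consistency and isoperimetric inequality
  expect_equal(m$mean_phase, m$optical_volume / m$area_um2, tolerance = 1e-12)
  expect_gte(m$perimeter_px^2, 4 * pi * m$area_px2)

  expect_error(measure_pollen(matrix(FALSE, 8, 8),
                              phase_map(matrix(0, 8, 8), "unwrapped")),
               "Empty mask")
})

test_that("marching-squares perimeter tracks the circle length", {
  ph <- centered_phantom(shape = c(128, 128), radius = 40, peak = 1)
  p <- holopollen:::marching_squares_perimeter(ph$true_mask)
  expect_equal(p, 2 * pi * 40, tolerance = 0.12 * 2 * pi * 40)
  # a single pixel has the minimal closed contour
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(holopollen:::marching_squares_perimeter(one), 4 * sqrt(2) / 2)
})

test_that("optical volume is additive and mean phase scales with peak", {
  meta <- optics_meta()
  a <- make_phantom("viable", shape = c(160, 160), center = c(45, 45),
                    radius = 22, peak_phase = 6)
  b <- make_phantom("viable", shape = c(160, 160), center = c(115, 110),
                    radius = 28, peak_phase = 9)
  pm <- phase_map(a$true_phase + b$true_phase, "unwrapped", meta = meta)
  va <- measure_pollen(a$true_mask, pm)$optical_volume
  vb <- measure_pollen(b$true_mask, pm)$optical_volume
  vab <- measure_pollen(a$true_mask | b$true_mask, pm)$optical_volume
  expect_equal(vab, va + vb, tolerance = 1e-9)

  m1 <- measure_pollen(a$true_mask, phase_map(a$true_phase, "unwrapped"))
  a3 <- make_phantom("viable", shape = c(160, 160), center = c(45, 45),
                     radius = 22, peak_phase = 18)
  m3 <- measure_pollen(a3$true_mask, phase_map(a3$true_phase, "unwrapped"))
  expect_equal(m3$mean_phase, 3 * m1$mean_phase, tolerance = 1e-9)
})

test_that("mean phase is invariant to a background offset removed before measuring", {
  ph <- centered_phantom(shape = c(96, 96), radius = 30, peak = 6)
  shifted <- phase_map(ph$true_phase + 0.8, "unwrapped")
  flat <- remove_background(shifted, mask = ph$true_mask)
  m0 <- measure_pollen(ph$true_mask, phase_map(ph$true_phase, "unwrapped"))
  m1 <- measure_pollen(ph$true_mask, flat)
  expect_equal(m1$mean_phase, m0$mean_phase, tolerance = 1e-6)
})

test_that("measure_phase_image chains segmentation and measurement", {
  ph <- centered_phantom(shape = c(192, 192), radius = 40, peak = 8)
  tbl <- measure_phase_image(phase_map(ph$true_phase, "unwrapped"))
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$mean_phase, phantom_mean_phase(ph), tolerance = 0.1)
})
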