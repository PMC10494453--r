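test_that("volume subtraction checks alignment", {
  v <- new_volume(array(rnorm(8^3), c(8, 8, 8)), 0.5)
  zero <- new_volume(array(0, c(8, 8, 8)), 0.5)
  expect_equal(as.numeric(subtract_volumes(v, v)), rep(0, 8^3))
  expect_equal(as.numeric(subtract_volumes(v, zero)), as.numeric(v))
  w <- new_volume(array(0, c(8, 8, 4)), 0.5)
  expect_error(subtract_volumes(v, w), class = "aneu_alignment_error")
  w2 <- new_volume(array(0, c(8, 8, 8)), 1)
  expect_error(subtract_volumes(v, w2), class = "aneu_alignment_error")
})

test_that("neck plane is recovered from the label interface", {
  ph <- reference_phantom()
  pl <- estimate_neck_plane(ph$truth$aneurysm_mask, ph$truth$vessel_mask)
  true_pl <- ph$truth$neck_plane
  angle <- acos(min(1, abs(sum(pl$normal * true_pl$normal)))) * 180 / pi
  expect_lt(angle, 5)
  expect_lt(sqrt(sum((pl$centroid - true_pl$centroid)^2)), 0.5)

  # swapping the masks flips the orientation
  pl_sw <- estimate_neck_plane(ph$truth$vessel_mask, ph$truth$aneurysm_mask)
  expect_lt(sum(pl$normal * pl_sw$normal), 0)

  empty <- new_volume(array(0L, dim(ph$truth$aneurysm_mask)), 0.5)
  expect_error(estimate_neck_plane(ph$truth$aneurysm_mask, empty),
               class = "aneu_isolated_mask")
})

test_that("measured morphometry recovers closed forms within a voxel diagonal", {
  tol <- sqrt(3) * 0.5
  # hemisphere R = 5, h = 5
  spec <- sample_phantom_spec(1, phantom_cohort_config(noise_sd = 0), seed = 5)
  spec$sphere_radius <- 5
  spec$cap_height <- 5 - 1e-9   # numerically a hemisphere
  spec$vessel_radius <- 2
  ph <- render_phantom(spec)
  pl <- estimate_neck_plane(ph$truth$aneurysm_mask, ph$truth$vessel_mask)
  m <- measure_morphometry(ph$truth$aneurysm_mask, pl)
  expect_lt(abs(m$size_mm - 5), tol)
  expect_lt(abs(m$height_mm - 5), tol)
  expect_lt(abs(m$neck_mm - 10), tol)
  expect_lt(abs(m$dome_mm - 10), tol)
  expect_lt(abs(m$volume_mm3 - 2 / 3 * pi * 125) / (2 / 3 * pi * 125), 0.05)

  # cap R = 4, h = 6
  ph2 <- reference_phantom()
  pl2 <- estimate_neck_plane(ph2$truth$aneurysm_mask, ph2$truth$vessel_mask)
  m2 <- measure_morphometry(ph2$truth$aneurysm_mask, pl2)
  expect_lt(abs(m2$size_mm - 6), tol)
  expect_lt(abs(m2$height_mm - 6), tol)
  expect_lt(abs(m2$neck_mm - 2 * sqrt(12)), tol)
  expect_lt(abs(m2$dome_mm - 8), tol)
  expect_lt(abs(m2$volume_mm3 - 72 * pi) / (72 * pi), 0.05)
})

test_that("degenerate sections are flagged, empty masks are errors", {
  dims <- c(16, 16, 16)
  single <- array(0L, dims)
  single[8, 8, 8] <- 1L
  single <- new_volume(single, 0.5)
  pl <- new_neck_plane(c(4, 4, 3.75), c(0, 0, 1))
  m <- measure_morphometry(single, pl)
  expect_equal(m$volume_mm3, 0.125)
  expect_true(is.nan(m$neck_mm))
  expect_true(is.nan(m$dome_mm))

  empty <- new_volume(array(0L, dims), 0.5)
  expect_error(measure_morphometry(empty, pl),
               class = "aneu_measurement_error")
})

test_that("prediction measurement filters speckle and detects empties", {
  ph <- reference_phantom()
  clean <- measure_from_prediction(ph$truth$aneurysm_mask,
                                   ph$truth$vessel_mask)
  direct <- measure_morphometry(
    ph$truth$aneurysm_mask,
    estimate_neck_plane(ph$truth$aneurysm_mask, ph$truth$vessel_mask))
  expect_equal(clean$size_mm, direct$size_mm)
  expect_equal(clean$volume_mm3, direct$volume_mm3)

  noisy <- ph$truth$aneurysm_mask
  noisy[2, 2, 60] <- 1L   # spurious far voxel
  withspeck <- measure_from_prediction(new_volume(array(as.integer(noisy),
                                                        dim(noisy)), 0.5),
                                       ph$truth$vessel_mask)
  expect_equal(withspeck$size_mm, clean$size_mm)
  expect_equal(withspeck$volume_mm3, clean$volume_mm3)

  expect_error(measure_from_prediction(new_volume(array(0L, dim(noisy)), 0.5),
                                       ph$truth$vessel_mask),
               class = "aneu_no_aneurysm")
})

test_that("measurement is scale-equivariant on the same index mask", {
  ph <- reference_phantom()
  mask <- ph$truth$aneurysm_mask
  pl <- estimate_neck_plane(mask, ph$truth$vessel_mask)
  m1 <- measure_morphometry(mask, pl)
  k <- 2
  mask2 <- new_volume(array(as.integer(mask), dim(mask)), 0.5 * k)
  vk <- ph$truth$vessel_mask
  mask2v <- new_volume(array(as.integer(vk), dim(vk)), 0.5 * k)
  pl2 <- estimate_neck_plane(mask2, mask2v)
  m2 <- measure_morphometry(mask2, pl2)
  for (f in c("size_mm", "height_mm", "neck_mm", "dome_mm")) {
    expect_equal(m2[[f]], k * m1[[f]], tolerance = 1e-6)
  }
  expect_equal(m2$volume_mm3, k^3 * m1$volume_mm3, tolerance = 1e-12)
})

test_that("measurement is robust to a 30-degree rotation", {
  ph <- reference_phantom()
  dims <- dim(ph$truth$aneurysm_mask)
  set.seed(21)
  M <- aneumorph:::rotation_matrix(rnorm(3), 30 * pi / 180)
  ctr <- (dims - 1) / 2
  A <- cbind(M, ctr - M %*% ctr)
  rot <- function(mask) {
    v <- aneumorph:::.warp_resample(as.numeric(mask), as.integer(dims),
                                    as.integer(dims), A,
                                    matrix(numeric(0), 0, 3), TRUE, 0, FALSE)
    new_volume(array(as.integer(v), dims), 0.5)
  }
  am <- rot(ph$truth$aneurysm_mask)
  vm <- rot(ph$truth$vessel_mask)
  m0 <- measure_morphometry(
    ph$truth$aneurysm_mask,
    estimate_neck_plane(ph$truth$aneurysm_mask, ph$truth$vessel_mask))
  m1 <- measure_morphometry(am, estimate_neck_plane(am, vm))
  tol <- 2 * sqrt(3) * 0.5
  for (f in c("size_mm", "height_mm", "neck_mm", "dome_mm")) {
    expect_lt(abs(m1[[f]] - m0[[f]]), tol)
  }
})

test_that("chord-averaged diameter matches digitized disks of known radius", {
  for (r in c(2, 3, 5)) {
    ball <- digitized_ball(r)
    U <- aneumorph:::pick_orthonormal(c(0, 0, 1))
    px <- aneumorph:::plane_section(ball, rep(0.5, 3), c(12, 12, 12),
                                    c(0, 0, 1), U, 0, r + 1, 0.25)
    d <- aneumorph:::chord_average(px, 180, 0.25)
    expect_lt(abs(d - 2 * r), sqrt(3) * 0.5)
  }
})

test_that("height never exceeds size on random phantoms", {
  specs <- sample_phantom_spec(20, phantom_cohort_config(noise_sd = 0),
                               seed = 14)
  for (i in seq_len(nrow(specs))) {
    ph <- render_phantom(specs[i, ])
    pl <- estimate_neck_plane(ph$truth$aneurysm_mask, ph$truth$vessel_mask)
    m <- measure_morphometry(ph$truth$aneurysm_mask, pl)
    expect_lte(m$height_mm, m$size_mm + 1e-9)
  }
})
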