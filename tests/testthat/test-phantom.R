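test_that("spherical-cap closed forms match hand geometry", {
  m <- analytic_morphometry(tibble::tibble(id = "a", location = "ICA",
                                           sphere_radius = 4, cap_height = 6))
  expect_equal(m$height_mm, 6)
  expect_equal(m$size_mm, 6)
  expect_equal(m$dome_mm, 8)
  expect_equal(m$neck_mm, 2 * sqrt(12))
  expect_equal(m$volume_mm3, 72 * pi)

  hemi <- analytic_morphometry(tibble::tibble(sphere_radius = 5, cap_height = 5))
  expect_equal(hemi$size_mm, 5)
  expect_equal(hemi$neck_mm, 10)
  expect_equal(hemi$dome_mm, 10)
  expect_equal(hemi$volume_mm3, 2 / 3 * pi * 125)

  expect_error(analytic_morphometry(tibble::tibble(sphere_radius = 4,
                                                   cap_height = 9)),
               class = "aneu_geometry_error")
})

test_that("spec sampling is seeded, valid, and matches cohort frequencies", {
  s1 <- sample_phantom_spec(50, seed = 11)
  s2 <- sample_phantom_spec(50, seed = 11)
  expect_identical(s1, s2)

  m <- analytic_morphometry(s1)
  expect_true(all(m$size_mm >= 3 & m$size_mm <= 10))
  nrm <- cbind(s1$normal_x, s1$normal_y, s1$normal_z)
  ax <- cbind(s1$axis_x, s1$axis_y, s1$axis_z)
  expect_equal(rowSums(nrm^2), rep(1, 50), tolerance = 1e-9)
  expect_equal(rowSums(ax^2), rep(1, 50), tolerance = 1e-9)
  expect_true(all(abs(rowSums(nrm * ax)) < 0.99))

  big <- sample_phantom_spec(10000, seed = 12)
  freq <- table(factor(big$location, names(phantom_cohort_config()$location_probs))) / 10000
  expected <- phantom_cohort_config()$location_probs
  expect_true(all(abs(freq - expected) <= 0.02))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(phantom_cohort_config(size_range = c(8, 4)),
               class = "aneu_config_error")
  expect_error(phantom_cohort_config(cap_fullness_range = c(0.3, 0.6)),
               class = "aneu_config_error")
  expect_error(phantom_cohort_config(location_probs = c(A = 0.9, B = 0.5)),
               class = "aneu_config_error")
})

test_that("coil labels follow the catalog rounding of mean(dome, size)", {
  m <- tibble::tibble(dome_mm = 8, size_mm = 6)
  expect_equal(assign_first_coil(m, seed = 1, noise_sd = 0), 7)
  # clipping at the catalog ceiling
  expect_equal(round_to_catalog(0.5 * (10 + 10) + 2), 10)
  # 1 mm is 4 sd of the label noise: nearly all labels stay within the band
  big <- coil_cohort(1000, seed = 8)
  clean <- round_to_catalog(0.5 * (big$dome_mm + big$size_mm))
  expect_gte(mean(abs(big$coil_mm - clean) <= 1), 0.95)
})

test_that("rendering voxelizes the analytic geometry faithfully", {
  ph <- reference_phantom()
  truth <- ph$truth
  vox_volume <- sum(truth$aneurysm_mask) * prod(voxel_spacing(truth$aneurysm_mask))
  expect_lt(abs(vox_volume - 72 * pi) / (72 * pi), 0.05)

  # masks disjoint and nonempty
  expect_gt(sum(truth$aneurysm_mask), 0)
  expect_gt(sum(truth$vessel_mask), 0)
  expect_equal(sum(truth$aneurysm_mask * truth$vessel_mask), 0)

  # noise-free subtraction is exactly the contrast level inside structures
  sub <- subtract_volumes(ph$post, ph$pre)
  inside <- (truth$aneurysm_mask == 1) | (truth$vessel_mask == 1)
  expect_true(all(sub[inside] == 200))
  expect_true(all(sub[!inside] == 0))
})

test_that("voxelization error shrinks with spacing", {
  specs <- sample_phantom_spec(3, phantom_cohort_config(noise_sd = 0),
                               seed = 33)
  rel_err <- vapply(c(0.5, 0.25), function(sp) {
    mean(vapply(1:3, function(i) {
      vol_true <- analytic_morphometry(specs[i, ])$volume_mm3
      ph <- render_phantom(specs[i, ], shape = rep(32 / sp, 3), spacing = sp)
      abs(sum(ph$truth$aneurysm_mask) * sp^3 - vol_true) / vol_true
    }, numeric(1)))
  }, numeric(1))
  expect_lt(rel_err[1], 0.05)
  expect_lt(rel_err[2], rel_err[1])
})

test_that("a too-coarse grid is refused", {
  spec <- sample_phantom_spec(1, seed = 2)
  expect_error(render_phantom(spec, shape = c(16, 16, 16), spacing = 2),
               class = "aneu_resolution_error")
})

test_that("cohort generation writes a reproducible bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- generate_cohort(4, seed = 7, out_dir = d1)
  expect_equal(nrow(man$files), 4)
  expect_length(list.files(d1, pattern = "\\.nii\\.gz$"), 16)
  tab <- read_cases(file.path(d1, "cohort.csv"), require_coil = TRUE)
  expect_equal(nrow(tab), 4)

  generate_cohort(4, seed = 7, out_dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))

  expect_error(generate_cohort(2, seed = 1, out_dir = "/dev/null/nope"),
               class = "aneu_io_error")
})
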