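test_that("segmentation configuration is validated", {
  expect_error(seg_config(target_shape = c(60, 64, 64)),
               class = "aneu_config_error")
  expect_error(seg_config(loss_weights = c(0, 0)), class = "aneu_config_error")
  cfg <- seg_config(target_shape = c(224, 256, 256), levels = 4)
  expect_identical(cfg$target_shape, c(224L, 256L, 256L))
})

test_that("resampling preserves identity, constants, and round-trips a ball", {
  v <- new_volume(array(rnorm(16^3), c(16, 16, 16)), 0.5)
  expect_identical(resample_volume(v, c(16, 16, 16)), v)

  const <- new_volume(array(3.5, c(8, 8, 8)), 1)
  up <- resample_volume(const, c(16, 16, 16))
  expect_true(all(abs(up - 3.5) < 1e-12))
  expect_equal(voxel_spacing(up), rep(0.5, 3))  # world extent preserved

  ball <- digitized_ball(5, dims = c(32, 32, 32), spacing = 1,
                         center = c(16, 16, 16))
  up <- resample_volume(ball, c(64, 64, 64), method = "nearest")
  back <- resample_volume(up, c(32, 32, 32), method = "nearest")
  cc <- confusion_counts(array(as.integer(back > 0.5), c(32, 32, 32)), ball)
  expect_gte(seg_scores(cc)$dice, 0.95)
})

test_that("augmentation honours no-op, volume-preserving, and seeded contracts", {
  ph <- reference_phantom()
  vol <- subtract_volumes(ph$post, ph$pre)
  mask <- ph$truth$aneurysm_mask

  off <- aug_config(p_flip = 0, p_rotate = 0, p_zoom = 0, p_brightness = 0,
                    p_contrast = 0, p_elastic = 0)
  set.seed(1)
  out <- augment_pair(vol, mask, off)
  expect_equal(as.numeric(out$vol), as.numeric(vol))
  expect_equal(as.numeric(out$mask), as.numeric(mask))

  fliponly <- aug_config(p_flip = 1, p_rotate = 0, p_zoom = 0,
                         p_brightness = 0, p_contrast = 0, p_elastic = 0)
  set.seed(2)
  fl <- augment_pair(vol, mask, fliponly)
  expect_equal(sum(fl$mask), sum(mask))
  expect_true(all(fl$mask %in% c(0L, 1L)))

  full <- aug_config()
  set.seed(3); a1 <- augment_pair(vol, mask, full)
  set.seed(3); a2 <- augment_pair(vol, mask, full)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0L, 1L)))
  expect_identical(voxel_spacing(a1$vol), voxel_spacing(vol))
})

test_that("the combined loss reduces to its closed forms", {
  p <- array(0.5, c(4, 4, 4))
  t <- array(0L, c(4, 4, 4))
  expect_equal(exp_log_loss(p, t, w_ce = 1, w_dice = 0, gamma = 1), log(2))

  set.seed(9)
  pp <- array(runif(64, 0.01, 0.99), c(4, 4, 4))
  tt <- array(as.integer(runif(64) > 0.5), c(4, 4, 4))
  ce <- -mean(tt * log(pp) + (1 - tt) * log(1 - pp))
  expect_equal(exp_log_loss(pp, tt, w_ce = 1, w_dice = 0, gamma = 1), ce,
               tolerance = 1e-9)

  near <- ifelse(tt > 0.5, 1 - 1e-7, 1e-7)
  expect_lt(exp_log_loss(near, tt), 0.05)
  expect_error(exp_log_loss(pp, tt[1:10]), class = "aneu_alignment_error")
})

test_that("the C++ training loss agrees with the R loss on probabilities", {
  dims <- c(8L, 8L, 8L)
  set.seed(12)
  z <- rnorm(prod(dims))
  t <- as.numeric(runif(prod(dims)) > 0.8)
  zp <- aneumorph:::.ten_load(matrix(z, ncol = 1), dims)
  for (gamma in c(0.3, 1)) {
    lc <- aneumorph:::.sigmoid_loss(zp, dims, t, 0.5, 0.5, gamma, FALSE, FALSE)
    lr <- exp_log_loss(1 / (1 + exp(-z)), t, 0.5, 0.5, gamma)
    expect_equal(lc$loss, lr, tolerance = 1e-5)
  }
})

test_that("the U-Net has the configured shape and residual behaviour", {
  cfg <- seg_config(target_shape = c(32, 32, 32), levels = 4,
                    base_filters = 4, seed = 3)
  m <- build_unet(cfg)
  x <- array(rnorm(32^3), c(32, 32, 32))
  fw <- aneumorph:::unet_fwd(m, x, want_cache = TRUE)
  # bottom feature map is the input shape halved once per level: 32 -> 2^3
  expect_equal(fw$caches$up_in[[cfg$levels]]$dims_in, rep(2L, 3))
  probs <- aneumorph:::.sigmoid_probs(fw$logits, cfg$target_shape)
  expect_length(probs, 32^3)
  expect_true(all(probs > 0 & probs < 1))

  # zeroed convolutions reduce a same-width block to the identity shortcut
  blk <- aneumorph:::new_block(4L, 4L)
  blk$W1[] <- 0; blk$W2[] <- 0
  dims <- c(8L, 8L, 8L)
  xin <- matrix(abs(rnorm(prod(dims) * 4)), ncol = 4)  # nonnegative input
  xp <- aneumorph:::.ten_load(xin, dims)
  out <- aneumorph:::block_fwd(blk, xp, dims, 4L)
  expect_equal(aneumorph:::.ten_store(out$Y, dims), xin, tolerance = 1e-6)
})

test_that("training splits, learns, and predicts deterministically", {
  sim <- simulate_cohort(6, seed = 51)
  cfg <- seg_config(epochs = 2, batch_size = 2, seed = 4)
  sg <- train_segmenter(sim, cfg, aug_config(p_elastic = 0))
  expect_length(sg$train_idx, round(0.75 * 6))
  expect_length(intersect(sg$train_idx, sg$test_idx), 0)
  expect_setequal(c(sg$train_idx, sg$test_idx), 1:6)
  expect_lt(sg$history$loss[2], sg$history$loss[1])

  sg2 <- train_segmenter(sim, cfg, aug_config(p_elastic = 0))
  expect_identical(sg$train_idx, sg2$train_idx)
  expect_equal(sg$history$loss, sg2$history$loss)

  pm1 <- predict_mask(sg, sim$cases[[1]]$subtracted)
  pm2 <- predict_mask(sg, sim$cases[[1]]$subtracted)
  expect_identical(pm1, pm2)
  expect_true(all(pm1 %in% c(0L, 1L)))

  expect_error(train_segmenter(list(), cfg), class = "aneu_config_error")
})

test_that("case-level detection applies the component-size rule", {
  dims <- c(16, 16, 16)
  expect_false(detect_aneurysm(new_volume(array(0L, dims), 0.5)))

  blob <- array(0L, dims); blob[4:13, 4:13, 4:13] <- 1L
  expect_true(detect_aneurysm(new_volume(blob, 0.5)))

  specks <- array(0L, dims)
  pts <- cbind(seq(1, 16, by = 2)[1:9], seq(1, 16, by = 2)[1:9],
               seq(1, 16, by = 2)[1:9])
  specks[pts] <- 1L
  expect_false(detect_aneurysm(new_volume(specks, 0.5), min_voxels = 10))
})
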