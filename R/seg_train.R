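#' Resample a volume to a new grid shape
#'
#' Trilinear interpolation for images (the 3D analogue of bilinear
#' magnification), nearest-neighbour for masks. Cell-centred resampling: the
#' world extent is preserved and the spacing rescaled accordingly.
#'
#' @param vol `aneu_volume` (or array with spacing).
#' @param target_shape integer length-3.
#' @param method "trilinear" or "nearest".
#' @return resampled `aneu_volume`.
#' @export
resample_volume <- function(vol, target_shape,
                            method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  target_shape <- as.integer(target_shape)
  if (any(target_shape <= 0)) {
    stop_aneu("target shape must be positive", "aneu_config_error")
  }
  dims <- dim(vol)
  if (identical(dims, target_shape)) return(vol)
  sp <- voxel_spacing(vol)
  scale <- dims / target_shape
  A <- cbind(diag(scale), 0.5 * scale - 0.5)
  out <- .warp_resample(as.numeric(vol), as.integer(dims), target_shape, A,
                        matrix(numeric(0), 0, 3), method == "nearest", 0,
                        TRUE)
  new_volume(array(out, target_shape), sp * scale)
}

#' Augmentation configuration
#'
#' Random training-time perturbations: axis flips, small rotations, zooming,
#' brightness and contrast adjustment, and elastic deformation (a smooth
#' random displacement field from a coarse control grid). Spatial transforms
#' are applied identically to the image and its mask (mask resampled
#' nearest-neighbour, so it stays binary). All probabilities 0 gives the
#' identity.
#'
#' @param p_flip,p_rotate,p_zoom,p_brightness,p_contrast,p_elastic per-draw
#'   probabilities of each transform.
#' @param max_rotate_deg maximum rotation angle about a random axis.
#' @param zoom_range multiplicative zoom range.
#' @param brightness_frac additive shift as a fraction of the intensity sd.
#' @param contrast_range multiplicative contrast range about the mean.
#' @param elastic_amp_mm displacement amplitude of the elastic field.
#' @param elastic_grid control-grid resolution per axis.
#' @return list of class `aneu_aug_config`.
#' @export
aug_config <- function(p_flip = 0.5, p_rotate = 0.5, p_zoom = 0.5,
                       p_brightness = 0.5, p_contrast = 0.5, p_elastic = 0.5,
                       max_rotate_deg = 15, zoom_range = c(0.9, 1.1),
                       brightness_frac = 0.1, contrast_range = c(0.9, 1.1),
                       elastic_amp_mm = 1.5, elastic_grid = 4) {
  structure(as.list(environment()), class = "aneu_aug_config")
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Randomly augment a volume/mask pair
#'
#' @param vol image `aneu_volume`.
#' @param mask aligned binary `aneu_volume`.
#' @param config an [aug_config()].
#' @return list(vol, mask), same grid as the input.
#' @export
augment_pair <- function(vol, mask, config = aug_config()) {
  stopifnot(identical(dim(vol), dim(mask)))
  dims <- dim(vol)
  sp <- voxel_spacing(vol)
  M <- diag(3)
  spatial <- FALSE
  if (stats::runif(1) < config$p_flip) {
    fl <- sample(c(-1, 1), 3, replace = TRUE)
    if (any(fl < 0)) { M <- M %*% diag(fl); spatial <- TRUE }
  }
  if (stats::runif(1) < config$p_rotate) {
    ang <- stats::runif(1, -config$max_rotate_deg, config$max_rotate_deg) * pi / 180
    M <- M %*% rotation_matrix(stats::rnorm(3), ang)
    spatial <- TRUE
  }
  if (stats::runif(1) < config$p_zoom) {
    # output->source scale is the inverse of the zoom factor
    M <- M / stats::runif(1, config$zoom_range[1], config$zoom_range[2])
    spatial <- TRUE
  }
  disp <- matrix(numeric(0), 0, 3)
  if (stats::runif(1) < config$p_elastic) {
    g <- config$elastic_grid
    amp_vox <- config$elastic_amp_mm / sp
    disp <- sapply(1:3, function(k) {
      coarse <- array(stats::rnorm(g^3, 0, amp_vox[k]), c(g, g, g))
      as.numeric(resample_volume(new_volume(coarse, 1), dims))
    })
    spatial <- TRUE
  }
  v <- as.numeric(vol)
  m <- as.numeric(mask)
  if (spatial) {
    ctr <- (dims - 1) / 2
    A <- cbind(M, ctr - M %*% ctr)
    v <- .warp_resample(v, as.integer(dims), as.integer(dims), A, disp,
                        FALSE, stats::median(v), FALSE)
    m <- .warp_resample(m, as.integer(dims), as.integer(dims), A, disp,
                        TRUE, 0, FALSE)
  }
  if (stats::runif(1) < config$p_brightness) {
    v <- v + stats::runif(1, -1, 1) * config$brightness_frac * stats::sd(v)
  }
  if (stats::runif(1) < config$p_contrast) {
    f <- stats::runif(1, config$contrast_range[1], config$contrast_range[2])
    v <- mean(v) + f * (v - mean(v))
  }
  list(vol = new_volume(array(v, dims), sp),
       mask = new_volume(array(as.integer(m > 0.5), dims), sp))
}

#' Combined cross-entropy and exponential-logarithmic Dice loss
#'
#' \deqn{L = w_{ce} \, mean_i (-\log p_{true,i})^\gamma +
#'       w_{dice} \, (-\log S)^\gamma}
#' where `p_true` is the predicted probability of the observed voxel label and
#' S is the soft Dice score `(2 sum(p t) + 1) / (sum(p) + sum(t) + 1)`. With
#' `gamma = 1` and `w_dice = 0` it reduces to mean cross-entropy; `gamma < 1`
#' flattens well-classified regions, emphasising the hard ones.
#'
#' @param pred_probs predicted foreground probabilities in (0, 1).
#' @param target_mask binary target of the same shape.
#' @param w_ce,w_dice nonnegative term weights.
#' @param gamma exponent, > 0.
#' @return scalar loss.
#' @export
exp_log_loss <- function(pred_probs, target_mask, w_ce = 0.5, w_dice = 0.5,
                         gamma = 0.3) {
  p <- as.numeric(pred_probs)
  t <- as.numeric(target_mask)
  if (length(p) != length(t)) {
    stop_aneu("probability and target shapes differ", "aneu_alignment_error")
  }
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  p_true <- ifelse(t > 0.5, p, 1 - p)
  lce <- mean(pmax(-log(p_true), 1e-6)^gamma)
  s <- (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1)
  w_ce * lce + w_dice * pmax(-log(s), 1e-6)^gamma
}

normalize_volume <- function(v) {
  x <- as.numeric(v)
  (x - mean(x)) / (stats::sd(x) + 1e-8)
}

# hard-Dice of the current model on one case (inputs already on model grid)
heldout_dice <- function(model, vol, mask, config) {
  fw <- unet_fwd(model, normalize_volume(vol), want_cache = FALSE)
  pred <- .sigmoid_probs(fw$logits, config$target_shape) >= 0.5
  rm(fw)
  gc(FALSE)
  t <- as.numeric(mask) > 0.5
  tp <- sum(pred & t)
  denom <- 2 * tp + sum(pred & !t) + sum(!pred & t)
  if (denom == 0) 1 else 2 * tp / denom
}

#' Train the segmenter on a phantom cohort
#'
#' Splits cases into training/held-out sets (75/25 by default), optimises the
#' combined loss with Adam at the configured learning rate, applying random
#' augmentation to each training sample, and records per-epoch mean loss and
#' soft Dice. The learning rate steps down to a tenth for the final fifth of
#' the schedule, damping end-of-training oscillation of the held-out Dice.
#' Inputs are the subtracted volumes, standardised per volume; targets are
#' the aneurysm masks.
#'
#' @param cohort a cohort from [simulate_cohort()], or a list of cases each
#'   holding `subtracted` and `truth$aneurysm_mask`.
#' @param config an [seg_config()].
#' @param augment an [aug_config()]; pass probabilities 0 to disable.
#' @param eval_every evaluate mean Dice on the held-out split every this many
#'   epochs (`Inf` disables; the final epoch is always evaluated when a
#'   held-out split exists).
#' @param verbose print a line per epoch.
#' @return `aneu_segmenter`: model, history tibble (loss, soft Dice and,
#'   where evaluated, held-out Dice per epoch), train/test indices.
#' @export
train_segmenter <- function(cohort, config = seg_config(),
                            augment = aug_config(), eval_every = Inf,
                            verbose = FALSE) {
  cases <- if (!is.null(cohort$cases)) cohort$cases else cohort
  n <- length(cases)
  if (n < 2) stop_aneu("need at least 2 cases to train", "aneu_config_error")
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  set.seed(seeds[1])
  n_train <- round(config$train_frac * n)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)

  model <- build_unet(config)   # seeds itself from config$seed
  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  vols <- lapply(cases, function(cs) {
    v <- cs$subtracted %||% subtract_volumes(cs$post, cs$pre)
    v
  })
  masks <- lapply(cases, function(cs) cs$truth$aneurysm_mask)

  set.seed(seeds[2])
  history <- vector("list", config$epochs)
  bs <- config$batch_size
  decay_from <- config$epochs - max(1L, round(config$epochs / 5)) + 1L
  for (ep in seq_len(config$epochs)) {
    lr <- config$learning_rate * if (ep >= decay_from) 0.1 else 1
    ord <- sample(train_idx)
    if (!is.null(config$steps_per_epoch)) {
      ord <- ord[seq_len(min(length(ord), config$steps_per_epoch * bs))]
    }
    losses <- c(); dices <- c()
    for (b0 in seq(1, length(ord), by = bs)) {
      batch <- ord[b0:min(b0 + bs - 1, length(ord))]
      grad_acc <- NULL
      for (i in batch) {
        aug <- augment_pair(vols[[i]], masks[[i]], augment)
        x <- normalize_volume(aug$vol)
        fw <- unet_fwd(model, x, want_cache = TRUE)
        ls <- .sigmoid_loss(fw$logits, config$target_shape,
                            as.numeric(aug$mask),
                            config$loss_weights[1], config$loss_weights[2],
                            config$gamma, TRUE, TRUE)
        losses <- c(losses, ls$loss)
        dices <- c(dices, ls$soft_dice)
        g <- unet_bwd(model, fw$caches, ls$dZ)
        gf <- flatten_params(g)
        grad_acc <- if (is.null(grad_acc)) gf else {
          Map(`+`, grad_acc, gf[names(grad_acc)])
        }
        # drop the activation cache promptly: the C++ tensors behind the
        # external pointers are invisible to R's heap accounting, so without
        # periodic explicit collection they pile up across samples
        rm(aug, fw, ls, g)
        if (i %% 3 == 0) gc(FALSE)
      }
      gc(FALSE)
      grad_acc <- lapply(grad_acc, function(g) g / length(batch))
      st <- adam_step(flat, grad_acc[names(flat)], opt, lr)
      flat <- st$params
      opt <- st$state
      model$params <- unflatten_params(model$params, flat)
    }
    test_dice <- NA_real_
    if (length(test_idx) > 0 &&
        (ep %% eval_every == 0 || ep == config$epochs)) {
      test_dice <- mean(vapply(test_idx, function(i) {
        heldout_dice(model, vols[[i]], masks[[i]], config)
      }, numeric(1)))
      gc(FALSE)
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                    soft_dice = mean(dices),
                                    test_dice = test_dice)
    if (verbose) {
      message(sprintf("epoch %3d/%d  loss %.4f  soft dice %.3f%s",
                      ep, config$epochs, mean(losses), mean(dices),
                      if (is.na(test_dice)) "" else
                        sprintf("  held-out dice %.3f", test_dice)))
    }
  }
  structure(list(model = model, config = config,
                 history = dplyr::bind_rows(history),
                 train_idx = train_idx, test_idx = test_idx),
            class = "aneu_segmenter")
}

#' @export
print.aneu_segmenter <- function(x, ...) {
  h <- x$history
  cat(sprintf("<segmenter> %d epochs trained; final loss %.4f, soft dice %.3f\n",
              nrow(h), h$loss[nrow(h)], h$soft_dice[nrow(h)]))
  cat(sprintf("  split: %d train / %d held-out cases\n",
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Predict a binary aneurysm mask
#'
#' Standardises the input, resamples it to the model grid if needed, runs the
#' forward pass and thresholds the voxelwise probability at 0.5; the mask is
#' resampled back to the input grid (nearest-neighbour).
#'
#' @param segmenter a trained `aneu_segmenter` (or its `model`).
#' @param vol subtracted-angiography `aneu_volume`.
#' @return binary `aneu_volume` on the input grid.
#' @export
predict_mask <- function(segmenter, vol) {
  model <- if (inherits(segmenter, "aneu_segmenter")) segmenter$model else segmenter
  dims_in <- dim(vol)
  tgt <- model$config$target_shape
  v <- vol
  if (!identical(as.integer(dims_in), tgt)) v <- resample_volume(v, tgt)
  x <- normalize_volume(v)
  fw <- unet_fwd(model, x, want_cache = FALSE)
  probs <- .sigmoid_probs(fw$logits, model$config$target_shape)
  rm(fw)
  gc(FALSE)   # release the C++ activation tensors behind external pointers
  m <- new_volume(array(as.integer(probs >= 0.5), tgt), voxel_spacing(v))
  if (!identical(as.integer(dims_in), tgt)) {
    m <- resample_volume(m, dims_in, method = "nearest")
  }
  new_volume(array(as.integer(m), dims_in), voxel_spacing(vol))
}

#' Case-level aneurysm detection
#'
#' A case is called positive when the largest 26-connected component of the
#' predicted mask has at least `min_voxels` voxels, suppressing speck noise.
#'
#' @param mask binary mask.
#' @param min_voxels component-size threshold.
#' @return logical.
#' @export
detect_aneurysm <- function(mask, min_voxels = 10) {
  lab <- .cc_label(as.integer(mask != 0), as.integer(dim(mask)))
  if (max(lab) == 0) return(FALSE)
  max(tabulate(lab)) >= min_voxels
}
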