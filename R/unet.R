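#' Segmentation model configuration
#'
#' The reference-scale configuration magnifies inputs to 224 x 256 x 256,
#' trains with batch size 14 for 300 epochs of 400 steps at learning rate
#' 0.001, and reaches a 16 x 16 x 16 bottom feature map; that scale needs GPU
#' hardware. The desk default trains the same residual U-Net on 64^3 volumes
#' with 4 resolution levels (4^3 bottom map), 8 base filters, batch 4 and 10
#' epochs (about 240 Adam steps, past the convergence point of the phantom
#' task), which runs in minutes on one CPU core.
#'
#' @param target_shape input grid (must be divisible by 2^levels).
#' @param levels number of max-pool/up-convolution levels.
#' @param base_filters channels of the first encoder block; doubled per level.
#' @param group_norm_groups groups for group normalization (capped at the
#'   channel count per layer).
#' @param learning_rate Adam learning rate.
#' @param batch_size training batch size.
#' @param epochs training epochs.
#' @param steps_per_epoch optimisation steps per epoch; `NULL` means one full
#'   pass over the training cases.
#' @param loss_weights c(ce, dice) weights of the combined loss.
#' @param gamma exponent of the exponential-logarithmic loss terms.
#' @param train_frac training fraction of the case-level split.
#' @param seed master seed; fans out to split, weight-init and augmentation
#'   streams.
#' @return list of class `aneu_seg_config`.
#' @export
seg_config <- function(target_shape = c(64, 64, 64), levels = 4,
                       base_filters = 8, group_norm_groups = 8,
                       learning_rate = 0.001, batch_size = 4, epochs = 8,
                       steps_per_epoch = NULL, loss_weights = c(0.2, 0.8),
                       gamma = 0.3, train_frac = 0.75, seed = 1) {
  target_shape <- as.integer(target_shape)
  if (any(target_shape <= 0) || any(target_shape %% 2L^levels != 0L)) {
    stop_aneu("target_shape must be positive and divisible by 2^levels",
              "aneu_config_error")
  }
  if (any(loss_weights < 0) || sum(loss_weights) == 0) {
    stop_aneu("loss_weights must be nonnegative and not both zero",
              "aneu_config_error")
  }
  structure(list(target_shape = target_shape, levels = levels,
                 base_filters = base_filters,
                 group_norm_groups = group_norm_groups,
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, steps_per_epoch = steps_per_epoch,
                 loss_weights = loss_weights, gamma = gamma,
                 train_frac = train_frac, seed = seed),
            class = "aneu_seg_config")
}

he_mat <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

gn_groups <- function(channels, requested) min(requested, channels)

# convolutions inside blocks carry no bias: group norm follows each one and
# makes an additive bias an exactly dead parameter
new_block <- function(c_in, c_out) {
  b <- list(
    W1 = he_mat(27 * c_in, c_out, 27 * c_in),
    g1 = rep(1, c_out), be1 = numeric(c_out),
    W2 = he_mat(27 * c_out, c_out, 27 * c_out),
    g2 = rep(1, c_out), be2 = numeric(c_out)
  )
  if (c_in != c_out) b$Ws <- he_mat(c_in, c_out, c_in)
  b
}

#' Build an untrained residual 3D U-Net
#'
#' Encoder-decoder with skip connections. Each block is two 3x3x3 convolutions
#' with group normalization and ReLU and an additive residual shortcut (a 1x1
#' projection where channel counts differ). The encoder downsamples by 2x2x2
#' max pooling per level, the decoder upsamples by transposed convolution, and
#' a final 1x1 convolution yields a voxelwise foreground probability via the
#' logistic function.
#'
#' @param config an [seg_config()].
#' @return list of class `aneu_unet` with `config` and `params`.
#' @export
build_unet <- function(config = seg_config()) {
  stopifnot(inherits(config, "aneu_seg_config"))
  set.seed(config$seed)
  L <- config$levels
  cs <- config$base_filters * 2L^(0:L)
  params <- list(enc = vector("list", L), dec = vector("list", L),
                 up = vector("list", L))
  for (l in seq_len(L)) {
    params$enc[[l]] <- new_block(if (l == 1) 1L else cs[l - 1], cs[l])
  }
  params$bottom <- new_block(cs[L], cs[L + 1])
  for (l in seq_len(L)) {
    c_above <- cs[l + 1]
    params$up[[l]] <- list(W = he_mat(c_above, 8 * cs[l], c_above),
                           b = numeric(cs[l]))
    params$dec[[l]] <- new_block(2L * cs[l], cs[l])
  }
  # prevalence-logit bias initialisation: the sac occupies ~1% of the
  # volume, so starting the output near that prior removes the cold-start
  # plateau where the net first has to learn "all background"
  params$final <- list(W = matrix(stats::rnorm(cs[1], sd = sqrt(1 / cs[1])),
                                  ncol = 1),
                       b = stats::qlogis(0.01))
  structure(list(config = config, params = params, channels = cs),
            class = "aneu_unet")
}

block_fwd <- function(p, xp, dims, groups) {
  c_out <- length(p$g1)
  ng <- gn_groups(c_out, groups)
  h1 <- .conv3_fwd(xp, dims, p$W1)
  g1 <- .gn_fwd(h1, dims, ng, p$g1, p$be1, TRUE)
  r1 <- g1$Y
  h2 <- .conv3_fwd(r1, dims, p$W2)
  g2 <- .gn_fwd(h2, dims, ng, p$g2, p$be2, FALSE)
  sc <- if (is.null(p$Ws)) xp else .conv1_fwd(xp, p$Ws)
  y <- .add_relu_fwd(g2$Y, sc)
  list(Y = y, cache = list(X = xp, r1 = r1, g1 = g1, g2 = g2, Yout = y,
                           dims = dims))
}

# the incoming gradient dY is single-use in this graph and mutated in place;
# want_dx = FALSE skips the input gradient (first encoder block)
block_bwd <- function(p, cache, dY, groups, want_dx = TRUE) {
  c_out <- length(p$g1)
  ng <- gn_groups(c_out, groups)
  dims <- cache$dims
  dS <- .relu_bwd_inplace(dY, cache$Yout)
  bg2 <- .gn_bwd(dS, dS, cache$g2$xhat, dims, cache$g2$invstd, p$g2, ng, FALSE)
  bc2 <- .conv3_bwd(cache$r1, bg2$dX, dims, p$W2, TRUE)
  bg1 <- .gn_bwd(bc2$dX, cache$r1, cache$g1$xhat, dims, cache$g1$invstd,
                 p$g1, ng, TRUE)
  bc1 <- .conv3_bwd(cache$X, bg1$dX, dims, p$W1, want_dx)
  sc_grads <- NULL
  dX <- NULL
  if (is.null(p$Ws)) {
    if (want_dx) dX <- .axpy_inplace(bc1$dX, dS)
  } else {
    bsc <- .conv1_bwd(cache$X, dS, p$Ws)
    sc_grads <- list(Ws = bsc$dW)
    if (want_dx) dX <- .axpy_inplace(bc1$dX, bsc$dX)
  }
  grads <- list(W1 = bc1$dW, g1 = bg1$dgamma, be1 = bg1$dbeta,
                W2 = bc2$dW, g2 = bg2$dgamma, be2 = bg2$dbeta)
  list(dX = dX, grads = c(grads, sc_grads))
}

unet_fwd <- function(model, x, want_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  L <- cfg$levels
  dims <- cfg$target_shape
  xp <- .ten_load(matrix(as.numeric(x), ncol = 1), dims)
  skips <- vector("list", L)
  caches <- list(enc = vector("list", L), pool = vector("list", L),
                 dec = vector("list", L), up_in = vector("list", L))
  cur <- xp
  d <- dims
  for (l in seq_len(L)) {
    bf <- block_fwd(p$enc[[l]], cur, d, cfg$group_norm_groups)
    skips[[l]] <- bf$Y
    if (want_cache) caches$enc[[l]] <- bf$cache
    pl <- .pool_fwd(bf$Y, d)
    if (want_cache) caches$pool[[l]] <- list(idx = pl$idx, dims_in = d)
    cur <- pl$Y
    d <- d %/% 2L
  }
  bf <- block_fwd(p$bottom, cur, d, cfg$group_norm_groups)
  if (want_cache) caches$bottom <- bf$cache
  cur <- bf$Y
  for (l in rev(seq_len(L))) {
    if (want_cache) caches$up_in[[l]] <- list(X = cur, dims_in = d)
    up <- .upconv_fwd(cur, d, p$up[[l]]$W, p$up[[l]]$b)
    d <- d * 2L
    cat_ <- .concat_fwd(skips[[l]], up)
    bf <- block_fwd(p$dec[[l]], cat_, d, cfg$group_norm_groups)
    if (want_cache) caches$dec[[l]] <- bf$cache
    cur <- bf$Y
  }
  logits <- .final_fwd(cur, p$final$W, p$final$b)
  if (want_cache) caches$pre_final <- cur
  list(logits = logits, caches = if (want_cache) caches else NULL)
}

unet_bwd <- function(model, caches, dlogits) {
  p <- model$params
  cfg <- model$config
  L <- cfg$levels
  g <- list(enc = vector("list", L), dec = vector("list", L),
            up = vector("list", L))
  bfin <- .final_bwd(caches$pre_final, dlogits, p$final$W)
  g$final <- list(W = bfin$dW, b = bfin$db)
  dcur <- bfin$dX
  dskip <- vector("list", L)
  for (l in seq_len(L)) {
    bb <- block_bwd(p$dec[[l]], caches$dec[[l]], dcur, cfg$group_norm_groups)
    g$dec[[l]] <- bb$grads
    c_l <- length(p$dec[[l]]$g1)
    parts <- .split_cols(bb$dX, c_l)
    dskip[[l]] <- parts[[1]]
    bu <- .upconv_bwd(caches$up_in[[l]]$X, parts[[2]],
                      caches$up_in[[l]]$dims_in, p$up[[l]]$W)
    g$up[[l]] <- list(W = bu$dW, b = bu$db)
    dcur <- bu$dX
  }
  bb <- block_bwd(p$bottom, caches$bottom, dcur, cfg$group_norm_groups)
  g$bottom <- bb$grads
  dcur <- bb$dX
  for (l in rev(seq_len(L))) {
    dpool <- .pool_bwd(dcur, caches$pool[[l]]$idx, caches$pool[[l]]$dims_in)
    dsum <- .axpy_inplace(dpool, dskip[[l]])
    bb <- block_bwd(p$enc[[l]], caches$enc[[l]], dsum, cfg$group_norm_groups,
                    want_dx = l > 1)
    g$enc[[l]] <- bb$grads
    dcur <- bb$dX
  }
  g
}

# ---- flat parameter traversal for the optimiser ----------------------------

flatten_params <- function(p, path = character()) {
  if (is.list(p) && is.null(dim(p))) {
    out <- list()
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      out <- c(out, flatten_params(p[[nm]], c(path, nm)))
    }
    if (is.null(names(p))) {
      for (i in seq_along(p)) {
        out <- c(out, flatten_params(p[[i]], c(path, as.character(i))))
      }
    }
    out
  } else {
    stats::setNames(list(p), paste(path, collapse = "/"))
  }
}

assign_by_path <- function(p, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  expr <- "p"
  for (pt in parts) {
    expr <- if (grepl("^[0-9]+$", pt)) {
      sprintf("%s[[%s]]", expr, pt)
    } else {
      sprintf("%s[['%s']]", expr, pt)
    }
  }
  eval(parse(text = sprintf("%s <- value", expr)))
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

adam_step <- function(params_flat, grads_flat, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params_flat)) {
    gr <- grads_flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params_flat[[nm]] <- params_flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params_flat, state = state)
}

unflatten_params <- function(p, flat) {
  for (nm in names(flat)) p <- assign_by_path(p, nm, flat[[nm]])
  p
}
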