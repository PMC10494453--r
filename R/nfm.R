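#' Round a diameter to the coil catalog
#'
#' Commercial framing coils come in 0.5 mm steps; the catalog spans 1-10 mm.
#' Nearest catalog value, ties rounding up, clipped to the catalog ends.
#'
#' @param d diameters in mm.
#' @return catalog diameters in mm.
#' @export
round_to_catalog <- function(d) {
  if (any(!is.finite(d))) {
    stop_aneu("diameter must be finite", "aneu_value_error")
  }
  pmin(10, pmax(1, floor(d * 2 + 0.5) / 2))
}

#' NFM configuration
#'
#' Desk-scale hyperparameters for the neural factorization machine: small
#' embeddings and one hidden layer train in seconds on a CPU at cohort sizes
#' around 10^2.
#'
#' @param n_bins quantile bins per continuous morphometric feature.
#' @param embedding_dim embedding dimension.
#' @param hidden_sizes sizes of the hidden layers on the bi-interaction.
#' @param dropout dropout rate on the bi-interaction vector during training.
#' @param learning_rate Adam learning rate.
#' @param epochs full-batch training epochs.
#' @param folds cross-validation folds.
#' @param train_frac training fraction of the derivation split.
#' @param seed RNG seed.
#' @return list of class `aneu_nfm_config`.
#' @export
nfm_config <- function(n_bins = 10, embedding_dim = 8, hidden_sizes = 64,
                       dropout = 0.1, learning_rate = 0.01, epochs = 200,
                       folds = 5, train_frac = 0.8, seed = 1) {
  if (folds < 2 || embedding_dim < 1) {
    stop_aneu("folds must be >= 2 and embedding_dim >= 1", "aneu_config_error")
  }
  structure(as.list(environment()), class = "aneu_nfm_config")
}

nfm_features <- c("size_mm", "height_mm", "neck_mm", "dome_mm", "volume_mm3")
nfm_locations <- c("Acom/ACA", "ICA", "MCA", "PC")

#' Fit the sparse feature encoder
#'
#' Each continuous morphometric feature is discretised into quantile bins
#' (breaks fitted on the supplied training records only) and the location
#' class is one-hot; a case becomes one active index per feature field. An
#' extra reserved index beyond the named vocabulary absorbs location levels
#' unseen at fit time.
#'
#' @param records tibble with the five morphometry columns and `location`.
#' @param n_bins quantile bins per continuous feature.
#' @return encoder of class `aneu_nfm_encoder`; `$vocabulary` counts the named
#'   indices (bins plus seen locations).
#' @export
encode_features <- function(records, n_bins = 10) {
  if (nrow(records) < n_bins) {
    stop_aneu("need at least n_bins records to fit quantile bins",
              "aneu_config_error")
  }
  breaks <- lapply(nfm_features, function(f) {
    x <- records[[f]]
    if (any(is.na(x))) stop_aneu(sprintf("NA in feature %s", f),
                                 "aneu_value_error")
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE))
    br[-c(1, length(br))]
  })
  names(breaks) <- nfm_features
  levels_seen <- nfm_locations[nfm_locations %in% unique(records$location)]
  if (length(levels_seen) == 0) levels_seen <- nfm_locations
  n_per_field <- c(vapply(breaks, function(b) length(b) + 1L, integer(1)),
                   location = length(levels_seen))
  structure(list(breaks = breaks, levels = levels_seen,
                 n_per_field = n_per_field,
                 offsets = cumsum(c(0, utils::head(n_per_field, -1))),
                 vocabulary = sum(n_per_field),
                 n_bins = n_bins),
            class = "aneu_nfm_encoder")
}

#' Transform records into active feature indices
#'
#' @param encoder an `aneu_nfm_encoder`.
#' @param records tibble of cases.
#' @return integer matrix, one row per case, one active (1-based) index per
#'   feature field; unseen locations map to the reserved unknown index
#'   `vocabulary + 1`.
#' @export
transform_features <- function(encoder, records) {
  n <- nrow(records)
  idx <- matrix(0L, n, length(encoder$n_per_field))
  for (j in seq_along(nfm_features)) {
    f <- nfm_features[j]
    x <- records[[f]]
    if (any(is.na(x))) stop_aneu(sprintf("NA in feature %s", f),
                                 "aneu_value_error")
    idx[, j] <- encoder$offsets[j] + findInterval(x, encoder$breaks[[f]]) + 1L
  }
  jl <- length(nfm_features) + 1
  loc <- match(records$location, encoder$levels)
  idx[, jl] <- ifelse(is.na(loc), encoder$vocabulary + 1L,
                      encoder$offsets[jl] + loc)
  idx
}

#' Build an untrained neural factorization machine
#'
#' Prediction = global bias + sum of per-index linear weights + a linear
#' read-out of a ReLU hidden layer applied to the bi-interaction pooling of
#' the active-index embeddings, `0.5 * ((sum v)^2 - sum v^2)` elementwise.
#' With a single active feature the bi-interaction is exactly zero; with all
#' embeddings zero the prediction reduces to bias + linear terms.
#'
#' @param config an [nfm_config()].
#' @param vocabulary_size named vocabulary size from the encoder (one reserved
#'   unknown row is added internally).
#' @return list of class `aneu_nfm`.
#' @export
build_nfm <- function(config, vocabulary_size) {
  set.seed(config$seed)
  V <- vocabulary_size + 1L   # + reserved unknown index
  k <- config$embedding_dim
  H <- config$hidden_sizes[1]
  structure(list(
    config = config,
    w0 = 0, w = numeric(V),
    emb = matrix(stats::rnorm(V * k, sd = 0.01), V, k),
    Wh = matrix(stats::rnorm(k * H, sd = sqrt(2 / k)), k, H),
    bh = numeric(H),
    wo = stats::rnorm(H, sd = sqrt(1 / H))
  ), class = "aneu_nfm")
}

nfm_forward <- function(model, idx, drop_mask = NULL) {
  n <- nrow(idx)
  k <- ncol(model$emb)
  S <- matrix(0, n, k); Q <- matrix(0, n, k)
  lin <- rep(model$w0, n)
  for (f in seq_len(ncol(idx))) {
    E <- model$emb[idx[, f], , drop = FALSE]
    S <- S + E
    Q <- Q + E * E
    lin <- lin + model$w[idx[, f]]
  }
  Z <- 0.5 * (S * S - Q)
  Zt <- if (is.null(drop_mask)) Z else Z * drop_mask
  Hpre <- sweep(Zt %*% model$Wh, 2, model$bh, `+`)
  Hact <- pmax(Hpre, 0)
  yhat <- lin + as.numeric(Hact %*% model$wo)
  list(yhat = yhat, S = S, Z = Z, Zt = Zt, Hact = Hact)
}

nfm_fit <- function(model, idx, y, config) {
  n <- nrow(idx)
  nf <- ncol(idx)
  k <- ncol(model$emb)
  adam <- function(x) list(m = x * 0, v = x * 0)
  st <- lapply(model[c("w0", "w", "emb", "Wh", "bh", "wo")], adam)
  t_ <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  for (ep in seq_len(config$epochs)) {
    dm <- NULL
    if (config$dropout > 0) {
      keep <- 1 - config$dropout
      dm <- matrix(stats::rbinom(n * k, 1, keep) / keep, n, k)
    }
    fw <- nfm_forward(model, idx, dm)
    r <- fw$yhat - y
    dy <- 2 * r / n
    g <- list(w0 = sum(dy), w = numeric(length(model$w)),
              emb = matrix(0, nrow(model$emb), k),
              Wh = NULL, bh = NULL, wo = NULL)
    g$wo <- as.numeric(t(fw$Hact) %*% dy)
    dH <- outer(dy, model$wo) * (fw$Hact > 0)
    g$Wh <- t(fw$Zt) %*% dH
    g$bh <- colSums(dH)
    dZt <- dH %*% t(model$Wh)
    dZ <- if (is.null(dm)) dZt else dZt * dm
    dS <- dZ * fw$S
    for (f in seq_len(nf)) {
      rs <- rowsum(dy, idx[, f])
      g$w[as.integer(rownames(rs))] <- g$w[as.integer(rownames(rs))] + rs
      E <- model$emb[idx[, f], , drop = FALSE]
      dE <- dS - dZ * E
      rsE <- rowsum(dE, idx[, f])
      rows <- as.integer(rownames(rsE))
      g$emb[rows, ] <- g$emb[rows, ] + rsE
    }
    t_ <- t_ + 1
    bc1 <- 1 - b1^t_; bc2 <- 1 - b2^t_
    for (nm in names(st)) {
      st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * g[[nm]]
      st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * g[[nm]]^2
      model[[nm]] <- model[[nm]] -
        lr * (st[[nm]]$m / bc1) / (sqrt(st[[nm]]$v / bc2) + eps)
    }
  }
  model
}

#' Predict a continuous first-coil diameter
#'
#' @param fit a fitted recommender from [train_nfm_cv()] (or a list with
#'   `model` and `encoder`).
#' @param records tibble of morphometry records.
#' @return numeric mm predictions (continuous; see [recommend_coil()] for
#'   catalog values).
#' @export
predict_diameter <- function(fit, records) {
  idx <- transform_features(fit$encoder, records)
  nfm_forward(fit$model, idx)$yhat
}

#' Recommend a catalog first-coil diameter
#'
#' Catalog rounding of [predict_diameter()]; this is the value that enters
#' [match_ratios()].
#'
#' @inheritParams predict_diameter
#' @return coil diameters in mm on the 0.5 mm catalog grid.
#' @export
recommend_coil <- function(fit, records) {
  round_to_catalog(predict_diameter(fit, records))
}

#' Train the coil recommender with cross-validated learning curve
#'
#' Splits the cases 80/20 into training and testing sets, runs k-fold
#' cross-validation on the training set (squared-error objective; encoder and
#' model refitted per fold on the in-fold cases only), records the per-fold
#' held-out general-match percentage, forms their mean and a t-based 95%
#' confidence interval, refits on the full training set, and computes the
#' testing-set percentage. The model is flagged as overfitting when the
#' testing percentage falls outside the confidence interval.
#'
#' @param cases tibble with morphometry columns, `location` and `coil_mm`.
#' @param config an [nfm_config()].
#' @return list of class `aneu_nfm_fit`: `model`, `encoder`,
#'   `learning_curve` (class `aneu_learning_curve`), `train_idx`, `test_idx`.
#' @export
train_nfm_cv <- function(cases, config = nfm_config()) {
  n <- nrow(cases)
  if (n < config$folds) stop_aneu("fewer cases than folds", "aneu_config_error")
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  set.seed(seeds[1])
  n_train <- round(config$train_frac * n)
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- cases[train_idx, ]

  fold_of <- rep_len(seq_len(config$folds), nrow(train))
  set.seed(seeds[2])
  fold_of <- sample(fold_of)
  fold_pct <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- train[fold_of != f, ]
    va <- train[fold_of == f, ]
    enc <- encode_features(tr, config$n_bins)
    m <- build_nfm(config, enc$vocabulary)
    m <- nfm_fit(m, transform_features(enc, tr), tr$coil_mm, config)
    rec <- recommend_coil(list(model = m, encoder = enc), va)
    fold_pct[f] <- match_ratios(rec, va$coil_mm)$general_ratio
  }
  enc <- encode_features(train, config$n_bins)
  set.seed(seeds[3])
  model <- build_nfm(config, enc$vocabulary)
  model <- nfm_fit(model, transform_features(enc, train), train$coil_mm, config)
  fit <- list(model = model, encoder = enc)
  test <- cases[test_idx, ]
  test_pct <- match_ratios(recommend_coil(fit, test), test$coil_mm)$general_ratio
  curve <- make_learning_curve(fold_pct, test_pct)
  structure(list(model = model, encoder = enc, learning_curve = curve,
                 train_idx = train_idx, test_idx = test_idx,
                 fold_of = fold_of, config = config),
            class = "aneu_nfm_fit")
}

# mean and t-based 95% CI of the per-fold percentages; the model is flagged
# as overfitting when the testing percentage falls outside the interval
# (a zero-variance interval degenerates to the mean, compared inclusively)
make_learning_curve <- function(fold_pct, test_pct) {
  k <- length(fold_pct)
  mean_pct <- mean(fold_pct)
  sd_pct <- stats::sd(fold_pct)
  half <- if (k > 1 && sd_pct > 0) {
    stats::qt(0.975, df = k - 1) * sd_pct / sqrt(k)
  } else 0
  ci <- c(mean_pct - half, mean_pct + half)
  structure(list(fold_percentages = fold_pct, train_mean = mean_pct,
                 ci95 = ci, test_percentage = test_pct,
                 overfit_flag = test_pct < ci[1] - 1e-12 ||
                   test_pct > ci[2] + 1e-12),
            class = "aneu_learning_curve")
}

#' @export
print.aneu_learning_curve <- function(x, ...) {
  cat(sprintf(
    "<learning curve> fold general-match %.3f (95%% CI %.3f-%.3f), test %.3f -> %s\n",
    x$train_mean, x$ci95[1], x$ci95[2], x$test_percentage,
    if (x$overfit_flag) "OVERFITTING suspected" else "no overfitting"))
  invisible(x)
}

#' @export
print.aneu_nfm_fit <- function(x, ...) {
  cat(sprintf("<nfm fit> %d train / %d test cases, vocabulary %d\n",
              length(x$train_idx), length(x$test_idx), x$encoder$vocabulary))
  print(x$learning_curve)
  invisible(x)
}
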