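test_that("catalog rounding is nearest with ties up and clipping", {
  expect_equal(round_to_catalog(4.3), 4.5)
  expect_equal(round_to_catalog(0.2), 1)
  expect_equal(round_to_catalog(4.25), 4.5)
  expect_equal(round_to_catalog(12), 10)
  expect_equal(round_to_catalog(6.8), 7)
  expect_error(round_to_catalog(NaN), class = "aneu_value_error")
  set.seed(6)
  out <- round_to_catalog(runif(100, 0, 12))
  expect_true(all(out %in% seq(1, 10, by = 0.5)))
})

test_that("feature encoding bins by quantiles and one-hots locations", {
  # median split of (1,2,3,4) puts the lower half in bin 0
  rec <- tibble::tibble(size_mm = c(1, 2, 3, 4), height_mm = c(1, 2, 3, 4),
                        neck_mm = c(1, 2, 3, 4), dome_mm = c(1, 2, 3, 4),
                        volume_mm3 = c(1, 2, 3, 4),
                        location = c("ICA", "ICA", "MCA", "PC"))
  enc <- encode_features(rec, n_bins = 2)
  idx <- transform_features(enc, rec)
  expect_equal(idx[, 1] - min(idx[, 1]), c(0L, 0L, 1L, 1L))

  # repeat transform of the same rows is identical
  expect_identical(idx, transform_features(enc, rec))

  # 5 continuous features x 10 bins + 4 locations -> vocabulary 54
  set.seed(17)
  rec2 <- tibble::tibble(size_mm = runif(40), height_mm = runif(40),
                         neck_mm = runif(40), dome_mm = runif(40),
                         volume_mm3 = runif(40),
                         location = rep(c("Acom/ACA", "ICA", "MCA", "PC"), 10))
  enc2 <- encode_features(rec2, n_bins = 10)
  expect_equal(enc2$vocabulary, 54)

  # unseen category maps to the reserved unknown index
  odd <- rec2[1, ]
  odd$location <- "never-seen"
  expect_equal(transform_features(enc2, odd)[, 6], enc2$vocabulary + 1L)

  rec_na <- rec2
  rec_na$size_mm[3] <- NA
  expect_error(transform_features(enc2, rec_na), class = "aneu_value_error")
})

test_that("the NFM reduces to its linear part and zeroes single interactions", {
  cfg <- nfm_config(seed = 2)
  m <- build_nfm(cfg, 54)
  m$emb[] <- 0
  idx <- matrix(c(3L, 14L, 25L, 36L, 47L, 51L), 1, 6)
  fw <- aneumorph:::nfm_forward(m, idx)
  expect_equal(fw$yhat, m$w0 + sum(m$w[idx]), tolerance = 1e-12)

  # one active feature: the bi-interaction vanishes identically
  m2 <- build_nfm(cfg, 54)
  fw1 <- aneumorph:::nfm_forward(m2, matrix(7L, 1, 1))
  expect_true(all(abs(fw1$Z) < 1e-12))
  expect_length(fw1$yhat, 1)
})

test_that("cross-validated training recovers the coil rule without overfitting", {
  cases <- coil_cohort(153, seed = 3)
  fit <- train_nfm_cv(cases, nfm_config(seed = 5))

  expect_length(fit$train_idx, round(0.8 * 153))
  expect_length(intersect(fit$train_idx, fit$test_idx), 0)

  lc <- fit$learning_curve
  expect_length(lc$fold_percentages, 5)
  expect_true(lc$ci95[1] <= lc$train_mean && lc$train_mean <= lc$ci95[2])
  expect_gte(lc$test_percentage, 0.85)
  expect_false(lc$overfit_flag)

  # held-out general match on the untouched split
  test <- cases[fit$test_idx, ]
  mr <- match_ratios(recommend_coil(fit, test), test$coil_mm)
  expect_gte(mr$general_ratio, 0.85)

  # determinism and order invariance
  fit2 <- train_nfm_cv(cases, nfm_config(seed = 5))
  expect_equal(fit$learning_curve$fold_percentages, lc$fold_percentages)
  p_fwd <- predict_diameter(fit, test)
  p_rev <- predict_diameter(fit, test[nrow(test):1, ])
  expect_equal(p_rev, rev(p_fwd))
  expect_true(all(recommend_coil(fit, test) %in% seq(1, 10, 0.5)))
})

test_that("a noise-free rule is recovered to the encoding resolution", {
  # with 10 quantile bins per feature the predictor is piecewise constant,
  # so recovery of the continuous rule is limited by the ~1.5 mm bin width
  # (about 0.75 mm mean absolute error), not by optimisation
  cases <- coil_cohort(153, seed = 9, noise_sd = 0)
  fit <- train_nfm_cv(cases, nfm_config(seed = 6))
  test <- cases[fit$test_idx, ]
  pred <- predict_diameter(fit, test)
  rule <- 0.5 * (test$dome_mm + test$size_mm)
  expect_lt(mean(abs(pred - rule)), 1.0)
  # on the catalog grid, the recommendation matches the rounded rule within
  # the clinical band for (almost) every held-out case
  mr <- match_ratios(recommend_coil(fit, test), round_to_catalog(rule))
  expect_gte(mr$general_ratio, 0.9)
})

test_that("permuting the labels destroys the recommendation signal", {
  cases <- coil_cohort(153, seed = 3)
  fit <- train_nfm_cv(cases, nfm_config(seed = 5))
  test <- cases[fit$test_idx, ]
  honest <- match_ratios(recommend_coil(fit, test), test$coil_mm)$general_ratio

  perm <- cases
  set.seed(99)
  perm$coil_mm <- sample(perm$coil_mm)
  fitp <- train_nfm_cv(perm, nfm_config(seed = 5))
  testp <- perm[fitp$test_idx, ]
  broken <- match_ratios(recommend_coil(fitp, testp), testp$coil_mm)$general_ratio
  expect_lt(broken, honest)
  expect_lt(broken, 0.75)
})

test_that("fold assignment partitions the training set", {
  cases <- coil_cohort(60, seed = 13)
  cfg <- nfm_config(seed = 7, epochs = 20)
  fit <- train_nfm_cv(cases, cfg)
  folds <- fit$fold_of
  expect_length(folds, length(fit$train_idx))
  expect_setequal(unique(folds), 1:5)
  expect_error(train_nfm_cv(cases[1:3, ], nfm_config()),
               class = "aneu_config_error")
})

test_that("a zero-variance learning curve degenerates to an inclusive point", {
  lc <- aneumorph:::make_learning_curve(rep(0.9, 5), 0.9)
  expect_equal(lc$ci95, c(0.9, 0.9))
  expect_false(lc$overfit_flag)
  lc2 <- aneumorph:::make_learning_curve(rep(0.9, 5), 0.8)
  expect_true(lc2$overfit_flag)
})
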