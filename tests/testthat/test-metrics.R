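test_that("confusion counts cover the exhaustive cases", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[2:3, 1, 1] <- 1L
  cc <- confusion_counts(a, b)
  expect_equal(cc$TP, 1); expect_equal(cc$FP, 1); expect_equal(cc$FN, 1)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 64)

  expect_equal(confusion_counts(a, a)$FP, 0)
  expect_equal(confusion_counts(a, a)$FN, 0)

  disj <- array(0L, c(4, 4, 4)); disj[4, 4, 4] <- 1L
  expect_equal(confusion_counts(a, disj)$TP, 0)

  ones <- array(1L, c(4, 4, 4))
  cc2 <- confusion_counts(ones, a)
  expect_equal(cc2$TP, 2); expect_equal(cc2$FP, 62); expect_equal(cc2$FN, 0)

  expect_error(confusion_counts(a, array(0L, c(4, 4, 2))),
               class = "aneu_alignment_error")
})

test_that("segmentation scores follow the standard and as-printed forms", {
  s <- seg_scores(tibble::tibble(TP = 30, FP = 10, FN = 10))
  expect_equal(s$dice, 0.75)
  expect_equal(s$precision, 0.75)
  expect_equal(s$recall, 0.75)
  expect_equal(s$f2, 0.75)

  s2 <- seg_scores(tibble::tibble(TP = 8, FP = 2, FN = 0))
  expect_equal(s2$precision, 0.8)
  expect_equal(s2$recall, 1)
  expect_equal(s2$dice, 16 / 18)

  # empty-vs-empty convention
  s3 <- seg_scores(tibble::tibble(TP = 0, FP = 0, FN = 0))
  expect_true(all(s3[, c("dice", "precision", "recall", "f2")] == 1))
  expect_true(s3$both_empty)

  # the as-printed recall doubles the numerator and can exceed 1
  sp <- seg_scores(tibble::tibble(TP = 8, FP = 2, FN = 0), as_printed = TRUE)
  expect_equal(sp$recall, 2)
  expect_equal(sp$f2, 5 * 0.8 * 2 / (4 * (0.8 + 2)))
})

test_that("score bounds and symmetry hold on random masks", {
  set.seed(40)
  for (i in 1:25) {
    a <- array(as.integer(runif(64) > runif(1)), c(4, 4, 4))
    b <- array(as.integer(runif(64) > runif(1)), c(4, 4, 4))
    s_ab <- seg_scores(confusion_counts(a, b))
    s_ba <- seg_scores(confusion_counts(b, a))
    expect_true(all(s_ab[, 1:4] >= 0 & s_ab[, 1:4] <= 1))
    expect_equal(s_ab$dice, s_ba$dice)
    expect_equal(s_ab$precision, s_ba$recall)
    if (s_ab$dice == 1) {
      cc <- confusion_counts(a, b)
      expect_equal(cc$FP + cc$FN, 0)
    }
  }
})

test_that("diagnosis accuracy is the agreement fraction", {
  expect_equal(diagnosis_accuracy(rep(TRUE, 5), rep(TRUE, 5)), 1)
  expect_equal(diagnosis_accuracy(c(rep(TRUE, 38), FALSE, TRUE),
                                  c(rep(TRUE, 39), FALSE)), 0.95)
  expect_equal(diagnosis_accuracy(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_error(diagnosis_accuracy(TRUE, logical(0)),
               class = "aneu_length_error")
})

test_that("ICC(2,1) matches an independent mean-squares oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(x, x), 1)

  y <- x + 0.1
  expect_equal(icc_agreement(x, y), icc_oracle(x, y), tolerance = 1e-12)
  expect_gt(icc_agreement(x, y), 0.95)

  yp <- c(3, 5, 1, 4, 2)   # fixed permutation, uncorrelated
  expect_equal(icc_agreement(x, yp), icc_oracle(x, yp), tolerance = 1e-12)
  expect_lt(icc_agreement(x, yp), 0.3)

  # symmetry and degenerate input
  set.seed(31)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(icc_agreement(a, b), icc_agreement(b, a))
  expect_warning(v <- icc_agreement(rep(1, 5), rep(1, 5)))
  expect_true(is.na(v))
  expect_error(icc_agreement(1:2, 1:2), class = "aneu_length_error")
})

test_that("match ratios count exact and within-band agreement", {
  expect_equal(unclass(match_ratios(c(4, 4.5), c(4, 4.5)))$absolute_ratio, 1)

  pred <- c(5, 5.5); act <- c(5, 7)
  mr <- match_ratios(pred, act)
  expect_equal(mr$n_absolute, 1)
  expect_equal(mr$n_general, 1)

  expect_error(match_ratios(1, c(1, 2)), class = "aneu_length_error")
})

test_that("absolute ratio never exceeds general; general grows with tolerance", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    pred <- round_to_catalog(runif(n, 1, 10))
    act <- round_to_catalog(runif(n, 1, 10))
    m0 <- match_ratios(pred, act, tolerance = 0)
    m1 <- match_ratios(pred, act, tolerance = 1)
    m2 <- match_ratios(pred, act, tolerance = 2)
    expect_lte(m1$absolute_ratio, m1$general_ratio)
    expect_lte(m0$general_ratio, m1$general_ratio)
    expect_lte(m1$general_ratio, m2$general_ratio)
    expect_equal(m1$n_absolute / m1$n_cases, m1$absolute_ratio)
  }
})
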