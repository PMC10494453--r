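#' Voxelwise confusion counts between two binary masks
#'
#' @param pred_mask,true_mask aligned binary arrays/volumes.
#' @return single-row tibble: TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop_aneu("masks have different shapes", "aneu_alignment_error")
  }
  p <- as.integer(pred_mask != 0)
  t <- as.integer(true_mask != 0)
  tibble::tibble(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t))
}

#' Segmentation scores from confusion counts
#'
#' Dice = 2TP / (2TP + FP + FN) and Precision = TP / (TP + FP). By default
#' Recall = TP / (TP + FN) and F2 = 5 P R / (4 P + R), the standard forms.
#' `as_printed = TRUE` instead reproduces the variant forms
#' Recall = 2TP / (TP + FN) and F2 = 5 P R / (4 (P + R)) exactly as printed in
#' some reports (note the printed recall can exceed 1). When both masks are
#' empty (TP = FP = FN = 0) every score is 1 by convention, so aneurysm-free
#' negatives do not poison cohort averages.
#'
#' @param counts tibble with TP, FP, FN columns (rows = cases).
#' @param as_printed use the as-printed recall/F2 variants.
#' @return tibble with dice, precision, recall, f2 (one row per input row).
#' @export
seg_scores <- function(counts, as_printed = FALSE) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  both_empty <- (TP + FP + FN) == 0
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  dice <- safe(2 * TP, 2 * TP + FP + FN)
  precision <- safe(TP, TP + FP)
  recall <- if (as_printed) safe(2 * TP, TP + FN) else safe(TP, TP + FN)
  f2 <- if (as_printed) {
    safe(5 * precision * recall, 4 * (precision + recall))
  } else {
    safe(5 * precision * recall, 4 * precision + recall)
  }
  out <- tibble::tibble(dice = dice, precision = precision,
                        recall = recall, f2 = f2)
  out[both_empty, ] <- 1
  out$both_empty <- both_empty
  out
}

#' Case-level diagnosis accuracy
#'
#' Fraction of cases where the predicted presence/absence flag agrees with
#' the true flag.
#'
#' @param pred_flags,true_flags logical vectors of equal length.
#' @return fraction in \[0, 1\].
#' @export
diagnosis_accuracy <- function(pred_flags, true_flags) {
  if (length(pred_flags) != length(true_flags) || length(pred_flags) < 1) {
    stop_aneu("flag vectors must be nonempty and of equal length",
              "aneu_length_error")
  }
  mean(pred_flags == true_flags)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between two
#' measurement sources (e.g. pipeline vs analytic truth, or model vs
#' clinician), computed from the two-way mean-squares decomposition:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with k = 2 raters. Values above 0.8 are conventionally read as good
#' consistency.
#'
#' @param x,y paired measurements from the two sources (length n >= 3).
#' @return ICC estimate in (-Inf, 1]; `NA` (with a warning) when all values
#'   are identical across subjects, where the coefficient is undefined.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) {
    stop_aneu("x and y must be paired", "aneu_length_error")
  }
  n <- length(x)
  if (n < 3) stop_aneu("ICC needs at least 3 subjects", "aneu_length_error")
  M <- cbind(x, y)
  k <- 2
  grand <- mean(M)
  if (max(M) - min(M) < .Machine$double.eps^0.5) {
    warning("ICC undefined: no variance across subjects")
    return(NA_real_)
  }
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_total <- sum((M - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Absolute and general match ratios for coil-diameter recommendations
#'
#' A case is an absolute match when the recommended diameter equals the actual
#' one exactly (both on the 0.5 mm catalog grid; a 1e-6 mm numeric tolerance
#' absorbs float noise), and a general match when the difference is within
#' `tolerance` (default the clinical +/- 1 mm band).
#'
#' @param predicted,actual coil diameters in mm, equal length.
#' @param tolerance general-match band in mm.
#' @return single-row tibble of class `aneu_match_report`: n_cases,
#'   n_absolute, n_general, absolute_ratio, general_ratio, tolerance.
#' @export
match_ratios <- function(predicted, actual, tolerance = 1.0) {
  if (length(predicted) != length(actual) || length(predicted) < 1) {
    stop_aneu("predicted and actual must be nonempty and of equal length",
              "aneu_length_error")
  }
  d <- abs(predicted - actual)
  n <- length(d)
  n_abs <- sum(d <= 1e-6)
  n_gen <- sum(d <= tolerance + 1e-9)
  out <- tibble::tibble(n_cases = n, n_absolute = n_abs, n_general = n_gen,
                        absolute_ratio = n_abs / n, general_ratio = n_gen / n,
                        tolerance = tolerance)
  class(out) <- c("aneu_match_report", class(out))
  out
}

#' @export
print.aneu_match_report <- function(x, ...) {
  cat(sprintf(
    "<match report> %d cases: absolute %.1f%% (%d/%d), general (+/- %g mm) %.1f%% (%d/%d)\n",
    x$n_cases, 100 * x$absolute_ratio, x$n_absolute, x$n_cases, x$tolerance,
    100 * x$general_ratio, x$n_general, x$n_cases))
  invisible(x)
}
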