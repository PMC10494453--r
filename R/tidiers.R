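#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a segmenter
#'
#' @param x an `aneu_segmenter`.
#' @param ... unused.
#' @return tibble with epoch, loss, soft_dice.
#' @export
tidy.aneu_segmenter <- function(x, ...) x$history

#' @rdname tidy.aneu_segmenter
#' @export
glance.aneu_segmenter <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), final_loss = h$loss[nrow(h)],
                 final_soft_dice = h$soft_dice[nrow(h)],
                 n_train = length(x$train_idx), n_test = length(x$test_idx))
}

#' Tidy a fitted coil recommender
#'
#' @param x an `aneu_nfm_fit`.
#' @param ... unused.
#' @return tibble with one row per cross-validation fold.
#' @export
tidy.aneu_nfm_fit <- function(x, ...) {
  lc <- x$learning_curve
  tibble::tibble(fold = seq_along(lc$fold_percentages),
                 general_match = lc$fold_percentages)
}

#' @rdname tidy.aneu_nfm_fit
#' @export
glance.aneu_nfm_fit <- function(x, ...) {
  lc <- x$learning_curve
  tibble::tibble(train_mean = lc$train_mean, ci95_low = lc$ci95[1],
                 ci95_high = lc$ci95[2], test_percentage = lc$test_percentage,
                 overfit_flag = lc$overfit_flag,
                 n_train = length(x$train_idx), n_test = length(x$test_idx),
                 vocabulary = x$encoder$vocabulary)
}

#' Plot a learning curve report
#'
#' Per-fold held-out general-match percentages with their mean and 95%
#' confidence band, against the testing-set percentage; the overfitting check
#' asks whether the test point stays inside the band.
#'
#' @param object an `aneu_learning_curve` (or `aneu_nfm_fit`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.aneu_learning_curve <- function(object, ...) {
  lc <- object
  df <- tibble::tibble(fold = seq_along(lc$fold_percentages),
                       pct = lc$fold_percentages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$pct)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = lc$ci95[1], ymax = lc$ci95[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = lc$train_mean, linetype = 2,
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = lc$test_percentage, colour = "firebrick") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(y = "general match ratio", x = "cross-validation fold",
                  title = sprintf("Learning curve: test %.2f vs CI [%.2f, %.2f] (%s)",
                                  lc$test_percentage, lc$ci95[1], lc$ci95[2],
                                  if (lc$overfit_flag) "overfitting" else "no overfitting"))
}

#' @export
autoplot.aneu_nfm_fit <- function(object, ...) {
  autoplot(object$learning_curve, ...)
}

#' Plot segmenter training history
#'
#' @param object an `aneu_segmenter`.
#' @param ... unused.
#' @return a ggplot of per-epoch loss and soft Dice.
#' @export
autoplot.aneu_segmenter <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, cols = c("loss", "soft_dice"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Segmenter training history")
}

#' Plot recommended vs actual coil diameters
#'
#' @param object an `aneu_match_report` built by [match_ratios()]; for the
#'   scatter, supply the raw vectors instead via [plot_coil_agreement()].
#' @param ... unused.
#' @return a ggplot bar summary of absolute/general match ratios.
#' @export
autoplot.aneu_match_report <- function(object, ...) {
  df <- tibble::tibble(kind = factor(c("absolute", "general"),
                                     levels = c("absolute", "general")),
                       ratio = c(object$absolute_ratio, object$general_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$ratio)) +
    ggplot2::geom_col(width = 0.5, fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$ratio)),
                       vjust = -0.4) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = NULL, y = "match ratio",
                  title = sprintf("Coil match ratios (n = %d, +/- %g mm band)",
                                  object$n_cases, object$tolerance))
}

#' Scatter of recommended vs actual first-coil diameters
#'
#' @param predicted,actual coil diameters in mm.
#' @param tolerance general-match band drawn around the identity.
#' @return a ggplot.
#' @export
plot_coil_agreement <- function(predicted, actual, tolerance = 1) {
  df <- tibble::tibble(actual = actual, predicted = predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = c(-tolerance, tolerance),
                         linetype = 3, colour = "grey60") +
    ggplot2::geom_count(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "actual first-coil diameter (mm)",
                  y = "recommended diameter (mm)")
}

#' @importFrom rlang .data
NULL
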