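#' End-to-end desk pipeline
#'
#' Runs the whole chain on synthetic phantoms: simulate a cohort, train the
#' segmenter, predict masks, measure morphometry from the predictions, train
#' the coil recommender on the measured features, recommend first-coil
#' diameters and evaluate. Emits a summary with four report blocks:
#' segmentation Dice statistics, per-feature ICC of measured vs analytic
#' morphometry, the coil match report, and the learning-curve report. The
#' master seed makes the whole chain reproducible.
#'
#' @param n_phantoms cohort size.
#' @param seed master seed.
#' @param shape,spacing rendering grid.
#' @param seg an [seg_config()] (its `seed` is overridden by `seed`).
#' @param nfm an [nfm_config()] (likewise).
#' @param augment an [aug_config()].
#' @param out_json optional path; when given, the summary (plus a config echo
#'   for provenance) is written there as JSON.
#' @return summary list with `dice`, `icc`, `match`, `learning_curve`.
#' @export
run_end_to_end <- function(n_phantoms = 40, seed = 1, shape = c(64, 64, 64),
                           spacing = 0.5, seg = seg_config(),
                           nfm = nfm_config(), augment = aug_config(),
                           out_json = NULL) {
  stage <- "simulate"
  result <- tryCatch({
    seeds <- derive_seeds(seed, 3)
    sim <- simulate_cohort(n_phantoms, seed = seeds[1], shape = shape,
                           spacing = spacing)
    stage <- "train-seg"
    seg$seed <- seeds[2]
    segm <- train_segmenter(sim, seg, augment)
    stage <- "segment+measure"
    test_cases <- sim$cases[segm$test_idx]
    dice <- numeric(0)
    measured <- list()
    for (cs in test_cases) {
      pm <- predict_mask(segm, cs$subtracted)
      cc <- confusion_counts(pm, cs$truth$aneurysm_mask)
      dice <- c(dice, seg_scores(cc)$dice)
      rec <- tryCatch(
        measure_from_prediction(pm, cs$truth$vessel_mask,
                                location = cs$spec$location, id = cs$spec$id),
        aneu_error = function(e) NULL)
      if (!is.null(rec)) measured[[length(measured) + 1]] <- rec
    }
    stage <- "icc"
    meas_tab <- dplyr::bind_rows(measured)
    feats <- nfm_features
    icc <- stats::setNames(rep(NA_real_, length(feats)), feats)
    if (nrow(meas_tab) >= 3) {
      truth_tab <- sim$table[match(meas_tab$id, sim$table$id), ]
      icc <- vapply(feats, function(f) {
        ok <- is.finite(meas_tab[[f]]) & is.finite(truth_tab[[f]])
        if (sum(ok) < 3) return(NA_real_)
        tryCatch(icc_agreement(meas_tab[[f]][ok], truth_tab[[f]][ok]),
                 warning = function(w) NA_real_)
      }, numeric(1))
    }
    stage <- "train-nfm"
    nfm$seed <- seeds[3]
    fit <- train_nfm_cv(sim$table, nfm)
    stage <- "recommend+evaluate"
    val <- sim$table[fit$test_idx, ]
    match <- match_ratios(recommend_coil(fit, val), val$coil_mm)
    list(
      dice = list(mean = mean(dice), sd = stats::sd(dice), n = length(dice)),
      icc = as.list(icc),
      match = as.list(match),
      learning_curve = list(
        fold_percentages = fit$learning_curve$fold_percentages,
        train_mean = fit$learning_curve$train_mean,
        ci95 = fit$learning_curve$ci95,
        test_percentage = fit$learning_curve$test_percentage,
        overfit_flag = fit$learning_curve$overfit_flag
      )
    )
  }, aneu_error = function(e) {
    stop_aneu(sprintf("pipeline failed at stage '%s': %s", stage,
                      conditionMessage(e)), "aneu_pipeline_error")
  })
  if (!is.null(out_json)) {
    echo <- list(n_phantoms = n_phantoms, seed = seed,
                 shape = as.integer(shape), spacing = spacing,
                 seg = unclass(seg), nfm = unclass(nfm))
    jsonlite::write_json(c(result, list(config = echo)), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# deterministic sub-seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}
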