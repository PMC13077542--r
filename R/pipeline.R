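# End-to-end in-memory pipeline over a synthetic study: the programmatic
# counterpart of the cmd_* stages, returning every intermediate product so
# benchmarks and tests can interrogate the whole chain.

#' Run the full semi-quantification pipeline on a synthetic study
#'
#' Executes the complete workflow on generated data: fit calibration
#' lines, derive anchor-relative experimental log10 IEs, split compounds
#' into training/test sets, clean descriptors and run RFE (over all
#' compounds by default, matching the original workflow's order of
#' operations; `rfe_on = "train"` restricts selection to the training
#' compounds), train the QSAR model, predict IEs for every compound,
#' invert them into concentrations at every calibration level, and compute
#' fold-error statistics.
#'
#' IE fold errors follow the symmetric convention (ratio of predicted to
#' experimental IE, or its inverse, whichever exceeds 1) and are reported
#' over all compounds as well as over the held-out test set.
#' Concentration errors are directional (predicted / nominal) per compound
#' and level, using the synthetic study's measured (noisy) peak areas.
#'
#' @param cfg a [generator_config()].
#' @param algorithm model family passed to [train_ie_model()].
#' @param subset_sizes,folds,repeats RFE settings (see [rfe_select()]).
#' @param train_frac fraction of compounds in the training set (default
#'   42/50).
#' @param rfe_on `"all"` (default) or `"train"`: which compounds feed the
#'   cleaning + RFE stage.
#' @param seed integer seed for split/selection/training (defaults to the
#'   generator seed).
#'
#' @return list with `study`, `fits`, `split`, `selection`, `model`,
#'   `train_metrics`, `test_metrics`, `pred_log_ie`, `ie_records` (fold
#'   errors, all compounds), `ie_summary`, `ie_summary_test`,
#'   `conc_records` (per compound x level), `conc_summary`, `by_level`
#'   (per-level error summaries, ascending level).
#' @export
run_synthetic_pipeline <- function(cfg = generator_config(),
                                   algorithm = "gbt",
                                   subset_sizes = c(5, 10, 18, 30, 60),
                                   folds = 5, repeats = 5,
                                   train_frac = 42 / 50,
                                   rfe_on = c("all", "train"),
                                   seed = cfg$seed) {
  rfe_on = match.arg(rfe_on)
  study <- simulate_ie_study(cfg)
  fits <- calibrate_study(study$calibration, study$registry,
                          anchor_id = "FHUEA")
  y <- stats::setNames(fits$exp_log_ie, fits$compound_id)
  ids <- rownames(study$descriptors)
  y <- y[ids]

  split <- make_split(ids, train_n = round(length(ids) * train_frac),
                      seed = seed)
  sel_ids <- if (rfe_on == "train") split$train_ids else ids
  sel <- select_features(study$descriptors[sel_ids, , drop = FALSE],
                         y[sel_ids], subset_sizes = subset_sizes,
                         folds = folds, repeats = repeats, seed = seed)
  keep <- sel$selected
  X <- study$descriptors[, keep, drop = FALSE]
  stopifnot(all(is.finite(X)))

  model <- train_ie_model(X[split$train_ids, , drop = FALSE],
                          y[split$train_ids], algorithm = algorithm,
                          seed = seed)
  train_metrics <- evaluate_ie_model(model, X[split$train_ids, , drop = FALSE],
                                     y[split$train_ids])
  test_metrics <- evaluate_ie_model(model, X[split$test_ids, , drop = FALSE],
                                    y[split$test_ids])

  pred_log_ie <- stats::setNames(stats::predict(model, X), ids)
  ie_records <- error_records(ids, 10^pred_log_ie, 10^y, type = "fold")
  ie_summary <- summarize_errors(ie_records)
  ie_summary_test <- summarize_errors(ie_records[
    ie_records$compound_id %in% split$test_ids, ])

  # invert predicted IEs into concentrations at every calibration level,
  # using the measured (noisy) areas of the synthetic series
  anchor_fit <- structure(
    as.list(fits[fits$compound_id == "FHUEA",
                 c("compound_id", "slope", "intercept", "r2")]),
    class = "calibration_fit")
  anchor_row <- list(id = "FHUEA", mw = registry_mw(study$registry, "FHUEA"))
  conc_records <- do.call(rbind, lapply(study$calibration, function(s) {
    id <- s$compound_id
    pred <- predict_concentration(
      s$areas, list(log_ie = pred_log_ie[[id]]),
      list(id = id, mw = registry_mw(study$registry, id)),
      anchor_fit, anchor_row)
    error_records(id, pred, s$levels, level = s$levels, type = "ratio")
  }))
  conc_summary <- summarize_errors(conc_records)
  by_level <- group_errors(conc_records, "level")

  list(study = study, fits = fits, split = split, selection = sel,
       model = model, train_metrics = train_metrics,
       test_metrics = test_metrics, pred_log_ie = pred_log_ie,
       ie_records = ie_records, ie_summary = ie_summary,
       ie_summary_test = ie_summary_test, conc_records = conc_records,
       conc_summary = conc_summary, by_level = by_level)
}

#' Interquartile dispersion of errors per concentration level
#'
#' Helper for the accuracy-vs-level diagnostic: at higher concentrations
#' the ignored calibration intercept and the area noise matter less, so
#' the spread of directional errors should shrink.
#'
#' @param conc_records an `error_records` data frame with a `level` column.
#' @return data frame with `level` (ascending) and `iqr` of the errors.
#' @export
level_dispersion <- function(conc_records) {
  lv <- sort(unique(conc_records$level))
  data.frame(
    level = lv,
    iqr = vapply(lv, function(l) {
      stats::IQR(conc_records$error[conc_records$level == l])
    }, numeric(1)))
}
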