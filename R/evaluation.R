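# Fold-error metrics for semi-quantitative predictions.
#
# Two error conventions are used side by side:
#   * symmetric IE fold error  max(pred/actual, actual/pred)  (always >= 1)
#   * directional concentration error  pred/actual             (may be < 1)
# Summaries report the median and mean of the raw errors plus a
# log-space RMS fold factor, 10^sqrt(mean(log10(error)^2)), which treats
# x-fold over- and under-prediction symmetrically and is always >= 1.

#' Symmetric fold error of a predicted ionization efficiency
#'
#' `max(pred/actual, actual/pred)`; equals 1 only for a perfect prediction.
#'
#' @param pred,actual strictly positive values (vectorized).
#' @return fold error(s), always >= 1.
#' @export
#'
#' @examples
#' ie_fold_error(2, 1)   # 2
#' ie_fold_error(1, 2)   # 2
ie_fold_error <- function(pred, actual) {
  if (any(!is.finite(pred)) || any(!is.finite(actual)) ||
      any(pred <= 0) || any(actual <= 0)) {
    stop("fold error requires strictly positive finite inputs")
  }
  pmax(pred / actual, actual / pred)
}

#' Directional concentration error
#'
#' `pred/actual`: values below 1 indicate under-prediction, above 1
#' over-prediction.
#'
#' @param pred predicted concentration(s), any real >= 0.
#' @param actual true concentration(s), strictly positive.
#' @return ratio(s) > 0 for positive predictions.
#' @export
concentration_error <- function(pred, actual) {
  if (any(!is.finite(actual)) || any(actual <= 0)) {
    stop("actual concentration must be strictly positive")
  }
  pred / actual
}

#' Build a table of error records
#'
#' @param compound_id compound ids (recycled if length 1).
#' @param predicted,actual numeric vectors.
#' @param level optional concentration level (ng/mL) per record.
#' @param type `"fold"` for the symmetric IE convention (error >= 1) or
#'   `"ratio"` for the directional concentration convention.
#' @return data frame of class `error_records` with columns `compound_id`,
#'   `level`, `predicted`, `actual`, `error`.
#' @export
error_records <- function(compound_id, predicted, actual, level = NA_real_,
                          type = c("fold", "ratio")) {
  type <- match.arg(type)
  err <- if (type == "fold") ie_fold_error(predicted, actual)
         else concentration_error(predicted, actual)
  structure(
    data.frame(compound_id = as.character(compound_id), level = level,
               predicted = predicted, actual = actual, error = err,
               stringsAsFactors = FALSE),
    class = c("error_records", "data.frame")
  )
}

#' Summarize a set of fold or ratio errors
#'
#' @param errors numeric vector of errors (ratios), or an `error_records`
#'   data frame.
#' @return list of class `error_summary`: `median`, `mean`, `rms_fold`
#'   (10^RMS of log10 errors, always >= 1), `rms` (plain RMS of the raw
#'   ratios, for reference), `min`, `max`, `n`.
#' @export
#'
#' @examples
#' summarize_errors(c(1.0, 1.2, 1.5))
summarize_errors <- function(errors) {
  if (is.data.frame(errors)) errors <- errors$error
  if (length(errors) == 0) stop("cannot summarize an empty error set")
  if (any(!is.finite(errors)) || any(errors <= 0)) {
    stop("errors must be positive and finite")
  }
  structure(
    list(median = stats::median(errors), mean = mean(errors),
         rms_fold = 10^sqrt(mean(log10(errors)^2)),
         rms = sqrt(mean(errors^2)),
         min = min(errors), max = max(errors), n = length(errors)),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "<error_summary> n=%d median %.3f mean %.3f rms_fold %.3f range [%.2f, %.2f]\n",
    x$n, x$median, x$mean, x$rms_fold, x$min, x$max))
  invisible(x)
}

#' Per-group error summaries
#'
#' @param records an `error_records` data frame.
#' @param by `"compound"` or `"level"`.
#' @return named list of `error_summary`, ordered by group key.
#' @export
group_errors <- function(records, by = c("compound", "level")) {
  by <- match.arg(by)
  key <- if (by == "compound") records$compound_id else records$level
  if (any(is.na(key))) stop("records are missing the grouping key '", by, "'")
  groups <- split(records$error, key)
  # numeric level keys sort numerically, compound ids lexically
  ord <- if (by == "level") order(as.numeric(names(groups)))
         else order(names(groups))
  lapply(groups[ord], summarize_errors)
}

#' Benchmark QSAR predictions against a reference quantification
#'
#' For compounds measured both by an isotope-dilution (IDMS) reference
#' method and by the standard-free QSAR route, computes the directional
#' concentration error of QSAR vs IDMS per compound, with display rounding
#' to two decimals (half-up), and an overall summary.
#'
#' @param certified named numeric vector of certified values (context only,
#'   carried through to the output).
#' @param idms named numeric vector of IDMS results; names are compound ids.
#' @param qsar_pred named numeric vector of QSAR-predicted concentrations.
#' @return list with `table` (data frame: compound_id, certified, idms,
#'   qsar_pred, error, error_2dp) and `summary` (an `error_summary`).
#' @export
reference_benchmark <- function(certified, idms, qsar_pred) {
  ids <- names(idms)
  if (is.null(ids) || !setequal(ids, names(qsar_pred)) ||
      !setequal(ids, names(certified))) {
    stop("certified, idms and qsar_pred must share the same compound names")
  }
  err <- concentration_error(qsar_pred[ids], idms[ids])
  tab <- data.frame(
    compound_id = ids,
    certified = unname(certified[ids]),
    idms = unname(idms[ids]),
    qsar_pred = unname(qsar_pred[ids]),
    error = unname(err),
    error_2dp = round_half_up(unname(err), 2),
    stringsAsFactors = FALSE)
  list(table = tab, summary = summarize_errors(tab$error))
}

# round-half-up to `digits` decimals (base round() is half-to-even); the
# epsilon shields exact decimal halves from binary representation error
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Fish-powder certified reference material benchmark data
#'
#' Loads the bundled nine-compound PFAS benchmark for the fish-powder
#' certified reference material GBW(E)100740: certified concentrations with
#' uncertainties, isotope-dilution (IDMS) results, and the concentrations
#' predicted by the QSAR ionization-efficiency route (all in ng/g).
#'
#' @return data frame with columns `compound_id`, `certified`,
#'   `uncertainty`, `idms`, `qsar_pred`.
#' @export
fish_powder_benchmark <- function() {
  path <- system.file("extdata", "fish_powder_pfas.csv", package = "ieqsar",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
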